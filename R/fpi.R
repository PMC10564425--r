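#' Ferroptosis potential index (FPI)
#'
#' The FPI of a sample is the enrichment score of the positive ferroptosis
#' regulator set minus that of the negative regulator set, taken from a
#' per-sample score matrix (ssGSEA by convention).
#'
#' @param scores a [score_matrix()] containing both regulator-set rows.
#' @param positive,negative names of the positive / negative regulator set
#'   rows in `scores`.
#' @return a data.frame of class `"fpi_vector"` with columns `sample_id`
#'   and `fpi`; attribute `standardized = FALSE`.
#' @export
compute_fpi <- function(scores, positive = "FRG_positive",
                        negative = "FRG_negative") {
  stopifnot(inherits(scores, "score_matrix"))
  miss <- setdiff(c(positive, negative), rownames(scores))
  if (length(miss))
    stop("score matrix is missing set row(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fpi <- as.numeric(scores[positive, ] - scores[negative, ])
  res <- data.frame(sample_id = colnames(scores), fpi = fpi,
                    stringsAsFactors = FALSE)
  attr(res, "standardized") <- FALSE
  class(res) <- c("fpi_vector", "data.frame")
  res
}

#' Min-max standardize an FPI vector to [0, 1]
#'
#' Rescales FPI values to `(x - min) / (max - min)`; monotone, so sample
#' ordering is preserved. A constant vector cannot be standardized.
#'
#' @param fpi an `"fpi_vector"` from [compute_fpi()].
#' @return the same object with `fpi` rescaled and `standardized = TRUE`.
#' @export
standardize_fpi <- function(fpi) {
  stopifnot(inherits(fpi, "fpi_vector"))
  rng <- range(fpi$fpi)
  if (diff(rng) == 0)
    stop("FPI is constant; cannot min-max standardize", call. = FALSE)
  fpi$fpi <- (fpi$fpi - rng[1L]) / diff(rng)
  attr(fpi, "standardized") <- TRUE
  fpi
}

#' Dichotomize samples at an FPI cutoff
#'
#' Samples with `fpi < cutoff` are labelled `"low"`, all others `"high"`
#' (a value exactly at the cutoff is high, matching the strict-less
#' convention of "FPI < cutoff is associated with improved survival").
#' Both groups must be non-empty.
#'
#' @param fpi an `"fpi_vector"`.
#' @param cutoff threshold strictly inside the observed FPI range.
#' @return the object with an added `group` column and a `cutoff` attribute.
#' @export
assign_groups <- function(fpi, cutoff) {
  stopifnot(inherits(fpi, "fpi_vector"), is.numeric(cutoff),
            length(cutoff) == 1L)
  grp <- ifelse(fpi$fpi < cutoff, "low", "high")
  if (length(unique(grp)) < 2L)
    stop("cutoff ", cutoff, " leaves a group empty (observed range ",
         paste(signif(range(fpi$fpi), 4), collapse = " .. "), ")",
         call. = FALSE)
  fpi$group <- grp
  attr(fpi, "cutoff") <- cutoff
  fpi
}
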
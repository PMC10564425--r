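#' Synthetic cohort configuration
#'
#' Parameters of the planted signal structure the analysis pipeline
#' assumes: a latent per-sample ferroptosis activity f ~ N(0, 1) that (i)
#' shifts positive ferroptosis-regulator genes up and negative regulators
#' down by `gamma` log2 units per unit f, (ii) drives each immune cell
#' type's marker block with a target gene-level correlation
#' `rho_by_celltype` (B cells strongest by default), and (iii) lowers the
#' exponential hazard by `beta` log-hazard units per unit f, with
#' independent uniform censoring.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_background_genes pure-noise genes appended to the matrix.
#' @param gamma FRG effect size, log2 units per unit latent factor.
#' @param rho_by_celltype named vector of target marker-gene correlations
#'   with the latent factor, |rho| < 1; defaults put B cells strongest,
#'   then CD8 T, T helper, Th17, NK CD56bright and NK CD56dim cells, with
#'   weak background correlation for the remaining types.
#' @param markers_per_type marker genes per immune cell type.
#' @param beta log-hazard decrease per unit latent factor (> 0 means higher
#'   ferroptosis activity, longer survival).
#' @param baseline_hazard events per day at f = 0.
#' @param censor_horizon censoring times are Uniform(0, censor_horizon) days.
#' @param noise_sd residual log2 SD of every simulated gene (> 0).
#' @param tumor_fraction fraction of samples labelled "tumor".
#' @param tumor_shift latent-factor mean shift of tumor samples (negative
#'   by default: tumors have lower ferroptosis activity).
#' @param seed root RNG seed; every random quantity flows from it.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 200,
                          n_background_genes = 500,
                          gamma = 1,
                          rho_by_celltype = NULL,
                          markers_per_type = 8,
                          beta = 0.5,
                          baseline_hazard = 1 / 1000,
                          censor_horizon = 3000,
                          noise_sd = 1,
                          tumor_fraction = 0.5,
                          tumor_shift = -0.5,
                          seed = 1) {
  if (is.null(rho_by_celltype)) {
    types <- immune_cell_types()
    rho_by_celltype <- stats::setNames(rep(0.10, length(types)), types)
    rho_by_celltype[c("B_cells", "CD8_T_cells", "T_helper_cells",
                      "Th17_cells", "NK_CD56bright_cells",
                      "NK_CD56dim_cells")] <-
      c(0.60, 0.45, 0.40, 0.35, 0.30, 0.25)
  }
  cfg <- list(n_samples = n_samples,
              n_background_genes = n_background_genes,
              gamma = gamma, rho_by_celltype = rho_by_celltype,
              markers_per_type = markers_per_type, beta = beta,
              baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon, noise_sd = noise_sd,
              tumor_fraction = tumor_fraction, tumor_shift = tumor_shift,
              seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
  if (is.null(names(cfg$rho_by_celltype)) ||
      any(!nzchar(names(cfg$rho_by_celltype))))
    stop("rho_by_celltype must be a named vector", call. = FALSE)
  if (any(abs(cfg$rho_by_celltype) >= 1))
    stop("|rho| must be < 1 for every cell type", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (cfg$censor_horizon <= 0) stop("censor_horizon must be > 0", call. = FALSE)
  if (cfg$markers_per_type < 1L) stop("markers_per_type must be >= 1", call. = FALSE)
  if (cfg$tumor_fraction < 0 || cfg$tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic expression / survival cohort
#'
#' Draws a cohort under the configuration's planted structure (see
#' [cohort_config()]): FRG rows shifted by +/- gamma * f, immune marker
#' blocks built as `rho * f + sqrt(1 - rho^2) * noise` scaled by
#' `noise_sd`, exponential survival with rate
#' `baseline_hazard * exp(-beta * f)` censored at Uniform(0, horizon), and
#' pure-noise background genes. Fully deterministic given the seed. The
#' simulated latent factor is kept as the annotation covariate
#' `latent_ferroptosis` so recovery can be validated.
#'
#' @param config a [cohort_config()].
#' @return list with `expr` (an [expression_matrix()], log2 scale), `ann`
#'   (a [cohort_annotations()]), and `sets` (a [gene_set_collection()] with
#'   FRG_positive, FRG_negative and one marker set per cell type).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  n_tumor <- round(config$tumor_fraction * n)
  group <- rep(c("tumor", "normal"), c(n_tumor, n - n_tumor))

  f <- stats::rnorm(n, mean = ifelse(group == "tumor", config$tumor_shift, 0),
                    sd = 1)

  frg <- frg_sets()
  frg_genes <- c(frg$FRG_positive, frg$FRG_negative)
  frg_sign <- rep(c(1, -1), c(length(frg$FRG_positive),
                              length(frg$FRG_negative)))
  markers <- synthetic_immune_marker_sets(config$markers_per_type)
  markers <- markers[names(config$rho_by_celltype)]
  marker_genes <- unlist(unclass(markers), use.names = FALSE)
  bg_genes <- if (config$n_background_genes > 0)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character(0)
  genes <- c(frg_genes, marker_genes, bg_genes)

  base <- stats::runif(length(genes), 4, 8)
  x <- matrix(NA_real_, length(genes), n, dimnames = list(genes, sample_ids))
  for (i in seq_along(frg_genes)) {
    x[i, ] <- base[i] + frg_sign[i] * config$gamma * f +
      stats::rnorm(n, sd = config$noise_sd)
  }
  row0 <- length(frg_genes)
  for (k in seq_along(markers)) {
    rho <- config$rho_by_celltype[[names(markers)[k]]]
    for (g in seq_len(config$markers_per_type)) {
      i <- row0 + (k - 1L) * config$markers_per_type + g
      x[i, ] <- base[i] + config$noise_sd *
        (rho * f + sqrt(1 - rho^2) * stats::rnorm(n))
    }
  }
  if (length(bg_genes)) {
    i0 <- row0 + length(marker_genes)
    x[(i0 + 1L):nrow(x), ] <- base[(i0 + 1L):nrow(x)] +
      matrix(stats::rnorm(length(bg_genes) * n, sd = config$noise_sd),
             length(bg_genes), n)
  }

  t_event <- stats::rexp(n, rate = config$baseline_hazard *
                           exp(-config$beta * f))
  t_cens <- stats::runif(n, 0, config$censor_horizon)
  ann <- cohort_annotations(data.frame(
    sample_id = sample_ids, group = group,
    time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
    event = as.integer(t_event <= t_cens),
    latent_ferroptosis = f, stringsAsFactors = FALSE))

  sets <- gene_set_collection(
    c(unclass(frg), unclass(markers)),
    c(attr(frg, "descriptions"), attr(markers, "descriptions")))
  list(expr = expression_matrix(x, "log2"), ann = ann, sets = sets)
}

#' Generate a two-group exponential survival fixture
#'
#' Small survival datasets for exercising Kaplan-Meier and log-rank code:
#' group "A" has exponential event rate `base_rate`, group "B" rate
#' `base_rate * rate_ratio`; both are censored at Uniform(0,
#' censor_horizon).
#'
#' @param n_per_group samples per group (>= 2).
#' @param rate_ratio hazard ratio of group B vs A.
#' @param base_rate events per day in group A.
#' @param censor_horizon censoring window in days.
#' @param seed RNG seed.
#' @return a [cohort_annotations()] with groups "A" and "B".
#' @export
generate_toy_survival <- function(n_per_group, rate_ratio = 1,
                                  base_rate = 0.01, censor_horizon = 200,
                                  seed = 1) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  set.seed(seed)
  n <- 2L * n_per_group
  rate <- rep(c(base_rate, base_rate * rate_ratio), each = n_per_group)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_horizon)
  cohort_annotations(data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    group = rep(c("A", "B"), each = n_per_group),
    time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE))
}
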
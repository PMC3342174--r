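#' Construct a synthetic-cohort generator configuration
#'
#' A generator configuration fully parameterizes a synthetic case-control
#' methylation cohort: group sizes, per-group per-CpG marginal mean/SD on
#' the percent scale, a latent Gaussian-copula correlation matrix per
#' group, SNP risk-allele frequencies with pairwise haplotype LD, additive
#' per-allele methylation effects, and a linear age model.
#'
#' @param cpgs character vector of CpG column labels (default: the seven
#'   proximal INS promoter CpGs, see [cpg_sites()]).
#' @param groups list of group specs, each a list with `label`, `n`, `mean`
#'   (named percent vector over `cpgs`), `sd` (named, > 0), and optionally
#'   `prop_male`, `age_mean`, `age_sd`, `covariates` (named list of
#'   `list(mean=, sd=)` for `hba1c` / `duration`).
#' @param latent_corr named list (by group label) of symmetric
#'   positive-semi-definite correlation matrices over `cpgs`.
#' @param snps data.frame with columns `id` and `risk_allele_freq` in
#'   \[0, 1\]; genotypes are coded as risk-allele counts 0/1/2.
#' @param ld_r symmetric matrix of pairwise haplotype (allele) correlations
#'   over the SNPs, entries in \[-1, 1\].
#' @param beta matrix (SNPs x CpGs) of percent methylation change per
#'   risk-allele copy; the generator centers the genotype so configured
#'   marginal means remain population means.
#' @param age_model list with `mean_age`, `sd_age` (years), optional
#'   `min_age`/`max_age` truncation bounds and `slope` (named percent/year
#'   per CpG, default 0).
#' @param seed integer root seed; all generator sub-streams derive from it.
#' @param name optional configuration label.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(cpgs = cpg_sites()$cpg, groups, latent_corr,
                             snps, ld_r, beta = NULL, age_model, seed = 1L,
                             name = "custom") {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(beta)) {
    beta <- matrix(0, nrow(snps), length(cpgs),
                   dimnames = list(snps$id, cpgs))
  }
  ld_r <- as.matrix(ld_r)
  dimnames(ld_r) <- list(snps$id, snps$id)
  if (is.null(age_model$min_age)) age_model$min_age <- 0
  if (is.null(age_model$max_age)) age_model$max_age <- Inf
  if (is.null(age_model$slope)) age_model$slope <- setNames(numeric(length(cpgs)), cpgs)
  slope <- setNames(numeric(length(cpgs)), cpgs)
  slope[names(age_model$slope)] <- unlist(age_model$slope)
  age_model$slope <- slope
  cfg <- structure(list(name = name, cpgs = cpgs, groups = groups,
                        latent_corr = latent_corr, snps = snps, ld_r = ld_r,
                        beta = beta, age_model = age_model,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every structural invariant: correlation matrices symmetric with
#' unit diagonal and positive semi-definite, marginal SDs positive, means
#' within \[0, 100\], group sizes at least 1, LD entries within \[-1, 1\]
#' with a positive-semi-definite matrix, allele frequencies in \[0, 1\].
#'
#' @param cfg a `generator_config`.
#' @return `cfg`, invisibly; stops with an informative error otherwise.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  cpgs <- cfg$cpgs
  if (length(cfg$groups) < 1) stop("at least one group is required")
  for (g in cfg$groups) {
    if (is.null(g$label) || is.null(g$n)) stop("each group needs 'label' and 'n'")
    if (g$n < 1) stop(sprintf("group '%s': n must be >= 1 (empty group rejected)", g$label))
    m <- unlist(g$mean)[cpgs]; s <- unlist(g$sd)[cpgs]
    if (anyNA(m) || anyNA(s))
      stop(sprintf("group '%s': mean/sd must be given for every CpG", g$label))
    if (any(m < 0 | m > 100))
      stop(sprintf("group '%s': marginal means must lie in [0, 100]", g$label))
    if (any(s <= 0))
      stop(sprintf("group '%s': marginal sds must be > 0", g$label))
    if (!g$label %in% names(cfg$latent_corr))
      stop(sprintf("no latent_corr matrix for group '%s'", g$label))
    check_corr_matrix(cfg$latent_corr[[g$label]], cpgs,
                      sprintf("latent_corr[%s]", g$label))
  }
  if (any(cfg$snps$risk_allele_freq < 0 | cfg$snps$risk_allele_freq > 1))
    stop("risk_allele_freq must lie in [0, 1]")
  check_corr_matrix(cfg$ld_r, cfg$snps$id, "ld_r", name_pair = TRUE)
  if (!identical(dim(cfg$beta), c(nrow(cfg$snps), length(cpgs))))
    stop("beta must be a SNPs x CpGs matrix")
  if (cfg$age_model$sd_age < 0) stop("sd_age must be >= 0")
  invisible(cfg)
}

# symmetric, unit diagonal, entries in [-1,1], PSD (eigenvalue floor -1e-8);
# name_pair: report the most extreme off-diagonal pair on PSD failure
check_corr_matrix <- function(R, labels, what, name_pair = FALSE, tol = 1e-8) {
  R <- as.matrix(R)
  if (nrow(R) != length(labels) || ncol(R) != length(labels))
    stop(sprintf("%s: expected a %d x %d matrix", what, length(labels), length(labels)))
  if (max(abs(R - t(R))) > tol) stop(sprintf("%s: matrix is not symmetric", what))
  if (max(abs(diag(R) - 1)) > tol) stop(sprintf("%s: diagonal must be 1", what))
  if (any(abs(R) > 1 + tol)) {
    idx <- which(abs(R) > 1 + tol, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: |r| > 1 for pair (%s, %s)", what,
                 labels[idx[1]], labels[idx[2]]))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    off <- abs(R); diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "%s: matrix is not positive semi-definite (min eigenvalue %.3g); largest off-diagonal entry at pair (%s, %s)",
      what, min(ev), labels[idx[1]], labels[idx[2]]))
  }
  invisible(TRUE)
}

#' Load a shipped generator configuration preset
#'
#' Three presets ship with the package as YAML files:
#' \describe{
#'   \item{`t1d_default`}{485 T1D cases vs 317 age-matched controls with the
#'     published per-CpG marginal means/SDs, the case CpG-CpG correlation
#'     structure (0.77 for -19/-135, 0.65 for -135/-234), rs689-driven
#'     additive methylation effects at CpGs -69/-102/-180/-206 and SNP LD.}
#'   \item{`t2d_default`}{132 T2D cases vs 186 controls with the published
#'     T2D marginals (CpG -19 lower, CpG -234 higher in cases) and no
#'     -19/-234 correlation.}
#'   \item{`aging_controls`}{an older control-only cohort with negative
#'     per-CpG age slopes, emulating the downward age trend of promoter
#'     methylation seen in older non-diabetic adults.}
#' }
#'
#' @param name preset name.
#' @return A validated `generator_config`.
#' @export
cohort_config <- function(name = c("t1d_default", "t2d_default", "aging_controls")) {
  name <- match.arg(name)
  path <- system.file("extdata", "config", paste0(name, ".yaml"),
                      package = "insmeth", mustWork = TRUE)
  read_cohort_config(path)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' @param path file path; format detected from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return A validated `generator_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cpgs <- unlist(raw$cpgs)
  snps <- data.frame(id = vapply(raw$snps, `[[`, "", "id"),
                     risk_allele_freq = vapply(raw$snps, `[[`, 0, "risk_allele_freq"),
                     stringsAsFactors = FALSE)
  latent <- lapply(raw$latent_corr, function(rows) {
    M <- do.call(rbind, lapply(rows, unlist))
    dimnames(M) <- list(cpgs, cpgs)
    M
  })
  beta <- matrix(0, nrow(snps), length(cpgs), dimnames = list(snps$id, cpgs))
  for (sid in names(raw$beta)) {
    b <- unlist(raw$beta[[sid]])
    beta[sid, names(b)] <- b
  }
  ld <- do.call(rbind, lapply(raw$ld_r, unlist))
  generator_config(cpgs = cpgs, groups = raw$groups, latent_corr = latent,
                   snps = snps, ld_r = ld, beta = beta,
                   age_model = raw$age_model,
                   seed = if (is.null(raw$seed)) 1L else raw$seed,
                   name = if (is.null(raw$name)) basename(path) else raw$name)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config '%s'>\n", x$name))
  for (g in x$groups) cat(sprintf("  group %-8s n = %d\n", g$label, g$n))
  cat(sprintf("  CpGs: %s\n", paste(x$cpgs, collapse = ", ")))
  cat(sprintf("  SNPs: %s\n", paste(x$snps$id, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
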
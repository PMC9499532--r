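#' Simulate trait observations from the growth-trajectory mixed model
#'
#' Generates data from
#' `y = beta0 + (beta1 + u_genot) * t + u_genoi + u_rep + e`, with
#' independent Gaussian random effects: per-genotype intercept deviations
#' `u_genoi ~ N(0, var_g_int)`, per-genotype slope deviations
#' `u_genot ~ N(0, var_g_slope)`, per-replicate deviations
#' `u_rep ~ N(0, var_rep)`, residual `e ~ N(0, var_resid)`.
#'
#' @param n_geno,n_rep numbers of genotypes and replicates (all crossed
#'   with all time points).
#' @param times time grid, hours since first imaging.
#' @param beta0,beta1 fixed intercept and slope (per hour).
#' @param var_g_int,var_g_slope,var_rep,var_resid variance components.
#' @param seed integer seed.
#' @return data.frame `y, t, genotype, replicate` plus the true random
#'   effects as attributes `u_genoi`, `u_genot`, `u_rep`.
#' @export
simulate_trait_observations <- function(n_geno = 93, n_rep = 6,
                                        times = seq(0, 336, by = 48),
                                        beta0 = 40, beta1 = 0.05,
                                        var_g_int = 4, var_g_slope = 0,
                                        var_rep = 1, var_resid = 1,
                                        seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  geno <- sprintf("g%03d", seq_len(n_geno))
  rep_id <- sprintf("r%02d", seq_len(n_rep))
  u_i <- rnorm(n_geno, 0, sqrt(var_g_int))
  u_t <- rnorm(n_geno, 0, sqrt(var_g_slope))
  u_r <- rnorm(n_rep, 0, sqrt(var_rep))
  d <- expand.grid(genotype = geno, replicate = rep_id, t = times,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(d$genotype, geno); ri <- match(d$replicate, rep_id)
  d$y <- beta0 + (beta1 + u_t[gi]) * d$t + u_i[gi] + u_r[ri] +
    rnorm(nrow(d), 0, sqrt(var_resid))
  attr(d, "u_genoi") <- setNames(u_i, geno)
  attr(d, "u_genot") <- setNames(u_t, geno)
  attr(d, "u_rep") <- setNames(u_r, rep_id)
  d
}

#' Fit the growth-trajectory mixed model to trait observations
#'
#' Restricted maximum likelihood fit (via lme4) of
#' `y ~ t + (1 | genotype) + (0 + t | genotype) + (1 | replicate)`:
#' trait and time as fixed effects; genotype intercept, genotype-by-time
#' slope, and replicate as independent random factors. The random-effect
#' deviations are the model's conditional means (BLUPs). A null
#' intercept-only model provides the baseline fit diagnostic.
#'
#' @param obs data.frame with columns `y`, `t` (hours), `genotype`,
#'   `replicate`; needs at least 2 genotypes, 2 replicates, 2 time points.
#' @return a `trait_model_fit`: `beta0`, `beta1`, named deviation vectors
#'   `u_genoi`, `u_genot`, `u_rep`, variance components `var_geno_int`,
#'   `var_geno_slope`, `var_rep`, `var_resid`, the observed `times` grid,
#'   `fit_diagnostics` (AIC of model and null, delta), and the lme4 fit in
#'   `$model`.
#' @export
fit_trait_model <- function(obs) {
  stopifnot(all(c("y", "t", "genotype", "replicate") %in% names(obs)))
  if (any(!is.finite(obs$y))) stop("non-finite trait values in y")
  if (length(unique(obs$genotype)) < 2)
    stop("a single genotype cannot separate genetic variance")
  if (length(unique(obs$replicate)) < 2) stop("need >= 2 replicates")
  if (length(unique(obs$t)) < 2) stop("need >= 2 time points")
  obs$genotype <- factor(obs$genotype)
  obs$replicate <- factor(obs$replicate)
  fit <- lme4::lmer(
    y ~ t + (1 | genotype) + (0 + t | genotype) + (1 | replicate),
    data = obs, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp_prefix, var) {
    v <- vc$vcov[startsWith(vc$grp, grp_prefix) &
                   !is.na(vc$var1) & vc$var1 == var]
    if (length(v) == 0) 0 else v[1]
  }
  # lme4 merges the intercept and slope genotype terms into one ranef
  # data.frame with columns "(Intercept)" and "t"
  re <- lme4::ranef(fit)
  g_int <- re$genotype["(Intercept)"]
  g_slo <- re$genotype["t"]
  null <- lm(y ~ 1, data = obs)
  out <- list(
    beta0 = unname(lme4::fixef(fit)[1]),
    beta1 = unname(lme4::fixef(fit)[2]),
    u_genoi = setNames(g_int[, 1], rownames(g_int)),
    u_genot = setNames(g_slo[, 1], rownames(g_slo)),
    u_rep = setNames(re$replicate[, 1], rownames(re$replicate)),
    var_geno_int = getvar("genotype", "(Intercept)"),
    var_geno_slope = getvar("genotype", "t"),
    var_rep = getvar("replicate", "(Intercept)"),
    var_resid = vc$vcov[vc$grp == "Residual"][1],
    times = sort(unique(obs$t)),
    fit_diagnostics = c(AIC_model = AIC(fit), AIC_null = AIC(null),
                        delta = AIC(null) - AIC(fit)),
    model = fit)
  class(out) <- "trait_model_fit"
  out
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf(paste0("<trait_model_fit: beta0=%.3f beta1=%.4f/h, ",
                     "%d genotypes, H2=%.3f>\n"),
              x$beta0, x$beta1, length(x$u_genoi),
              broad_sense_heritability(x)))
  invisible(x)
}

#' Per-genotype fitted trait values on a time grid
#'
#' Each genotype's expected trait value is exactly linear in time:
#' `(beta0 + u_genoi) + (beta1 + u_genot) * t`, evaluated by default on the
#' standard imaging grid 0, 48, ..., 336 h. These fitted values denoise
#' replicate variation and are the downstream analysis currency.
#'
#' @param fit a `trait_model_fit`.
#' @param times evaluation grid, hours.
#' @return data.frame: `genotype`, `intercept`, `slope`, and one
#'   `value_<t>h` column per grid point.
#' @export
fitted_values <- function(fit, times = seq(0, 336, by = 48)) {
  stopifnot(inherits(fit, "trait_model_fit"))
  geno <- names(fit$u_genoi)
  intercept <- fit$beta0 + fit$u_genoi
  slope <- fit$beta1 + fit$u_genot[geno]
  vals <- outer(slope, times) + intercept
  colnames(vals) <- sprintf("value_%gh", times)
  data.frame(genotype = geno, intercept = unname(intercept),
             slope = unname(slope), vals, row.names = NULL,
             check.names = FALSE)
}

#' Broad-sense heritability from variance components
#'
#' Fraction of total phenotypic variance associated with genotype on the
#' observed time grid. The genotype contribution at time `t` is
#' `var_geno_int + var_geno_slope * t^2` (independent intercept and slope
#' deviations), averaged over the grid:
#' `H2 = (var_geno_int + var_geno_slope * mean(t^2)) /
#'       (var_geno_int + var_geno_slope * mean(t^2) + var_rep + var_resid)`.
#'
#' @param fit a `trait_model_fit`, or a list with elements `var_geno_int`,
#'   `var_geno_slope`, `var_rep`, `var_resid`, `times`.
#' @return H-squared in `[0, 1]`.
#' @export
broad_sense_heritability <- function(fit) {
  var_g <- fit$var_geno_int + fit$var_geno_slope * mean(fit$times^2)
  tot <- var_g + fit$var_rep + fit$var_resid
  if (tot <= 0) stop("zero total variance")
  var_g / tot
}

#' Variance components achieving a target heritability
#'
#' Utility for simulation studies: given the non-genetic variances and the
#' split of genetic variance between intercept and slope, returns the
#' genetic components whose [broad_sense_heritability()] on `times` equals
#' `h2`.
#'
#' @param h2 target broad-sense heritability.
#' @param times time grid.
#' @param var_rep,var_resid non-genetic variance components.
#' @param slope_share fraction of the genetic variance carried by the slope
#'   term (on the grid).
#' @return list `var_g_int`, `var_g_slope`.
#' @export
h2_components <- function(h2, times = seq(0, 336, by = 48),
                          var_rep = 1, var_resid = 4, slope_share = 0.3) {
  stopifnot(h2 > 0, h2 < 1)
  var_g <- h2 / (1 - h2) * (var_rep + var_resid)
  list(var_g_int = (1 - slope_share) * var_g,
       var_g_slope = slope_share * var_g / mean(times^2))
}

#' Cluster genotype trait trajectories
#'
#' Between-group average linkage (UPGMA) hierarchical clustering of the
#' genotype-by-day trait matrix on Euclidean distances of per-day
#' standardized rows, with the tree cut at `cut_distance` (default 1.75).
#' Missing cells are imputed by the genotype's row mean (recorded in the
#' `imputed` attribute). Cluster labels are ordered by decreasing cluster
#' mean of the original values, so for gravity-angle trajectories cluster 1
#' is the shallowest (largest angle) group.
#'
#' @param m numeric matrix, genotypes in rows, days in columns.
#' @param cut_distance tree cut height.
#' @param standardize z-score each column before clustering.
#' @return named integer vector of cluster labels, one per genotype, with
#'   the `hclust` tree in attribute `"tree"`.
#' @export
cluster_trajectories <- function(m, cut_distance = 1.75,
                                 standardize = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 genotypes")
  imputed <- which(is.na(m), arr.ind = TRUE)
  if (nrow(imputed) > 0) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    m[imputed] <- rm_[imputed[, 1]]
  }
  z <- if (standardize) scale(m) else m
  z[is.nan(z)] <- 0   # constant columns
  hc <- hclust(dist(z), method = "average")
  labs <- cutree(hc, h = cut_distance)
  means <- tapply(rowMeans(m), labs, mean)
  new_order <- rank(-means, ties.method = "first")
  out <- setNames(as.integer(new_order[as.character(labs)]), rownames(m))
  attr(out, "tree") <- hc
  attr(out, "imputed") <- imputed
  out
}
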
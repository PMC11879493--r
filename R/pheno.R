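#' Shade-tolerance index from a paired shade/control plot record
#'
#' STI = (PH_shade/PH_control + AINL_shade/AINL_control) / 2, where AINL is
#' the average internode length PH/NN. Inputs are vectorised.
#'
#' @param ph_shade,nn_shade Plant height (cm) and main-stem node number of
#'   the shaded plot.
#' @param ph_control,nn_control The paired control plot.
#' @return STI values (dimensionless).
#' @examples
#' compute_sti(100, 10, 80, 10) # 1.25
#' compute_sti(120, 12, 80, 10) # 1.375
#' @export
compute_sti <- function(ph_shade, nn_shade, ph_control, nn_control) {
  vals <- c(ph_shade, ph_control)
  nns <- c(nn_shade, nn_control)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_config("plant heights must be finite and > 0")
  if (any(!is.finite(nns)) || any(nns < 1))
    stop_config("node numbers must be finite and >= 1")
  (ph_shade / ph_control +
      (ph_shade / nn_shade) / (ph_control / nn_control)) / 2
}

#' STI per plot pair from a long-format phenotype table
#'
#' Pairs shade and control plots by (line, env, rep) and applies
#' [compute_sti()] to each pair.
#'
#' @param plots Data frame with columns `line`, `env`, `rep`, `condition`
#'   (`"shade"` / `"control"`), `PH`, `NN`.
#' @return Data frame `line`, `env`, `rep`, `value` (one STI per pair).
#' @export
sti_table <- function(plots) {
  need <- c("line", "env", "rep", "condition", "PH", "NN")
  if (!all(need %in% names(plots)))
    stop_config("plots must have columns %s", paste(need, collapse = ", "))
  sh <- plots[plots$condition == "shade", ]
  ck <- plots[plots$condition == "control", ]
  ksh <- paste(sh$line, sh$env, sh$rep, sep = "\r")
  kck <- paste(ck$line, ck$env, ck$rep, sep = "\r")
  if (anyDuplicated(ksh) || anyDuplicated(kck))
    stop_config("duplicate (line, env, rep, condition) plot records")
  m <- match(ksh, kck)
  if (anyNA(m) || nrow(sh) != nrow(ck))
    stop_config("shade and control plots are not fully paired")
  data.frame(
    line = sh$line, env = sh$env, rep = sh$rep,
    value = compute_sti(sh$PH, sh$NN, ck$PH[m], ck$NN[m]),
    stringsAsFactors = FALSE
  )
}

#' Relative pith cell length per shade micrograph
#'
#' One RCL per shade image: the mean cell length of that image divided by
#' the pooled mean of all control-image cells (all cells pooled, not a
#' mean of image means — the two differ when image cell counts differ).
#'
#' @param cells Data frame with columns `condition` (`"shade"` /
#'   `"control"`), `image_id`, `length`; typically one line's records.
#' @return Data frame `image_id`, `value` (one RCL per shade image).
#' @examples
#' cells <- data.frame(
#'   condition = rep(c("shade", "shade", "control"), each = 2),
#'   image_id = rep(c("s1", "s2", "c1"), each = 2),
#'   length = c(55, 65, 75, 85, 38, 42)
#' )
#' compute_rcl(cells) # 60/40 = 1.5, 80/40 = 2.0
#' @export
compute_rcl <- function(cells) {
  stopifnot(all(c("condition", "image_id", "length") %in% names(cells)))
  if (any(cells$length <= 0)) stop_config("cell lengths must be > 0")
  sh <- cells[cells$condition == "shade", ]
  ck <- cells[cells$condition == "control", ]
  if (nrow(sh) == 0 || nrow(ck) == 0)
    stop_config("need at least one shade and one control image")
  acl_ck <- mean(ck$length)
  means <- tapply(sh$length, sh$image_id, mean)
  data.frame(image_id = names(means), value = as.numeric(means) / acl_ck,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RCL table per line with seeded subsampling
#'
#' Applies [compute_rcl()] per line and randomly retains `n_keep` values per
#' line (the field workflow measures many micrographs but carries a fixed
#' number of RCL values per line into analysis).
#'
#' @param cells Data frame with columns `line`, `condition`, `image_id`,
#'   `length`.
#' @param n_keep Number of RCL values retained per line (all kept if fewer).
#' @param seed Integer seed for the subsampling, or `NULL`.
#' @return Data frame `line`, `rep` (index within line), `value`.
#' @export
rcl_table <- function(cells, n_keep = 5, seed = NULL) {
  stopifnot("line" %in% names(cells))
  with_seed(seed, {
    out <- lapply(split(cells, cells$line), function(d) {
      v <- compute_rcl(d)$value
      if (length(v) > n_keep) v <- sample(v, n_keep)
      data.frame(line = d$line[1], rep = seq_along(v), value = v,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Variance components of a balanced line x environment x replicate layout
#'
#' Method-of-moments estimates from the expected mean squares of the
#' two-way random model (lines and environments random):
#' `MS_G = s2_eps + r*s2_ge + r*n*s2_g`, `MS_GE = s2_eps + r*s2_ge`,
#' `MS_err = s2_eps`. With a single environment the one-way model is used
#' and `s2_ge` is reported as 0 with `gei_estimable = FALSE`. Negative
#' moment estimates are truncated to 0 and flagged.
#'
#' @param values Data frame `line`, `value`, plus `env` and/or `rep`
#'   columns; the layout must be balanced.
#' @return Object of class `variance_components`: list with `sigma2_g`,
#'   `sigma2_ge`, `sigma2_eps`, `n_env`, `n_rep`, `mu`, `gei_estimable`,
#'   `truncated` (names of truncated components).
#' @export
anova_components <- function(values) {
  stopifnot(all(c("line", "value") %in% names(values)))
  line <- factor(values$line)
  env <- if ("env" %in% names(values)) factor(values$env) else factor(rep("E1", nrow(values)))
  y <- values$value
  a <- nlevels(line)
  n <- nlevels(env)
  tab <- table(line, env)
  r <- tab[1, 1]
  if (any(tab != r) || r < 1)
    stop_config("unbalanced line x env x rep layout (cell counts differ)")
  mu <- mean(y)
  truncated <- character(0)
  cell_means <- tapply(y, list(line, env), mean)
  line_means <- rowMeans(cell_means)
  env_means <- colMeans(cell_means)
  ss_err <- sum((y - cell_means[cbind(line, env)])^2)
  df_err <- a * n * (r - 1)
  if (n > 1) {
    ss_g <- n * r * sum((line_means - mu)^2)
    ss_ge <- r * sum((sweep(sweep(cell_means, 1, line_means), 2, env_means) + mu)^2)
    ms_g <- ss_g / (a - 1)
    ms_ge <- ss_ge / ((a - 1) * (n - 1))
    if (df_err == 0)
      stop_config("no replicate degrees of freedom: need r >= 2 with multiple environments")
    ms_err <- ss_err / df_err
    s2_eps <- ms_err
    s2_ge <- (ms_ge - ms_err) / r
    s2_g <- (ms_g - ms_ge) / (r * n)
    gei_estimable <- TRUE
  } else {
    if (r < 2) stop_config("single-environment layout needs r >= 2")
    ss_g <- r * sum((line_means - mu)^2)
    ms_g <- ss_g / (a - 1)
    ms_err <- ss_err / df_err
    s2_eps <- ms_err
    s2_ge <- 0
    s2_g <- (ms_g - ms_err) / r
    gei_estimable <- FALSE
  }
  if (s2_g < 0) { truncated <- c(truncated, "sigma2_g"); s2_g <- 0 }
  if (s2_ge < 0) { truncated <- c(truncated, "sigma2_ge"); s2_ge <- 0 }
  structure(
    list(sigma2_g = s2_g, sigma2_ge = s2_ge, sigma2_eps = s2_eps,
         n_env = n, n_rep = as.integer(r), mu = mu,
         gei_estimable = gei_estimable, truncated = truncated),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: s2_g = %.4g, s2_ge = %.4g, s2_eps = %.4g (n = %d env, r = %d rep)\n",
    x$sigma2_g, x$sigma2_ge, x$sigma2_eps, x$n_env, x$n_rep
  ))
  if (length(x$truncated))
    cat("  truncated at 0:", paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

#' Broad-sense heritability with optional GEI partition
#'
#' With GEI: D = s2_g + s2_ge/n + s2_eps/(n r); h2_main = s2_g / D,
#' h2_gei = (s2_ge/n) / D, h2_total = h2_main + h2_gei. Without GEI
#' (single environment): h2 = s2_g / (s2_g + s2_eps/r), h2_gei = 0.
#' The denominator D is the variance of line means, so mapped-QTL
#' contributions measured on line means are directly comparable.
#'
#' @param vc A [anova_components()] result (or compatible list).
#' @param with_gei Partition out the GEI share? Defaults to the layout's
#'   `gei_estimable` flag.
#' @return List `h2_total`, `h2_main`, `h2_gei` (proportions in [0, 1]).
#' @examples
#' vc <- list(sigma2_g = 2, sigma2_ge = 1, sigma2_eps = 3, n_env = 3,
#'            n_rep = 3, gei_estimable = TRUE)
#' heritability(vc) # h2_main 0.75, h2_gei 0.125, total 0.875
#' @export
heritability <- function(vc, with_gei = NULL) {
  with_gei <- with_gei %||% isTRUE(vc$gei_estimable)
  n <- vc$n_env
  r <- vc$n_rep
  if (with_gei) {
    D <- vc$sigma2_g + vc$sigma2_ge / n + vc$sigma2_eps / (n * r)
    if (D <= 0) stop_config("heritability undefined: denominator is 0")
    list(h2_total = (vc$sigma2_g + vc$sigma2_ge / n) / D,
         h2_main = vc$sigma2_g / D,
         h2_gei = (vc$sigma2_ge / n) / D)
  } else {
    D <- vc$sigma2_g + vc$sigma2_eps / r
    if (D <= 0) stop_config("heritability undefined: denominator is 0")
    h2 <- vc$sigma2_g / D
    list(h2_total = h2, h2_main = h2, h2_gei = 0)
  }
}

#' Genotypic coefficient of variation
#'
#' GCV = sigma_g / mu (reported as a proportion; multiply by 100 for %).
#'
#' @param sigma_g Genotypic standard deviation (trait units).
#' @param mu Population mean (trait units, non-zero).
#' @return The ratio.
#' @examples
#' gcv(0.2, 1.6) # 0.125
#' @export
gcv <- function(sigma_g, mu) {
  if (sigma_g < 0) stop_config("sigma_g must be >= 0")
  if (mu == 0) stop_config("GCV undefined for mu = 0")
  sigma_g / mu
}
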
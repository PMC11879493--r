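# locus score matrix: +1 for the P1 class, -1 for P2, 0 for residual
# heterozygotes (population-mean contribution)
locus_scores <- function(rils, gene_ids) {
  missing_ids <- setdiff(gene_ids, colnames(rils$source))
  if (length(missing_ids) > 0)
    stop_config("QTL not in genotypes: %s", paste(missing_ids, collapse = ", "))
  src <- rils$source[, gene_ids, drop = FALSE]
  s <- matrix(0, nrow(src), ncol(src), dimnames = dimnames(src))
  s[src == "P1"] <- 1
  s[src == "P2"] <- -1
  s
}

#' Simulate multi-environment indicator phenotypes for a RIL population
#'
#' Generates plot-level phenotype records under the two-way random model
#' y = mu + G_i + GE_ie + eps. Genetic values come from the architecture's
#' QTL (deviation-coded, `effect/2` per homozygous class); GEI effects and
#' the plot-level error variance are rescaled/solved so that the realized
#' heritability decomposition on the line-mean scale
#' (h2_main = s2_g / D, h2_gei = (s2_ge/n) / D with
#' D = s2_g + s2_ge/n + s2_eps/(n r)) matches the architecture's targets.
#'
#' In `"raw"` mode the same latent indicator is back-constructed into plant
#' height / node number pairs: node numbers are equal integers in the two
#' conditions, control heights come from a baseline distribution, and
#' `PH_shade = PH_control * indicator`, so [compute_sti()] on the emitted
#' records reproduces the latent plot indicator exactly.
#'
#' @param rils A [simulate_rils()] population.
#' @param arch A [trait_architecture()].
#' @param mode `"indicator"` (plot-level indicator values) or `"raw"`
#'   (additionally back-construct PH/NN plot records).
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `sim_phenotypes`: list with `indicator`
#'   (data frame `line`, `env`, `rep`, `value`), `plots` (raw mode only:
#'   `line`, `env`, `rep`, `condition`, `PH`, `NN`), and `truth` (genetic
#'   values, GEI matrix, realized variance components used for generation).
#' @examples
#' map <- make_map(2, 10, 100, 2, seed = 1)
#' rils <- simulate_rils(map, 100, 6, seed = 2)
#' arch <- assign_architecture(map, 5, 0.1, 0.05, 0.67, 0.18, seed = 3)
#' ph <- simulate_phenotypes(rils, arch, seed = 4)
#' head(ph$indicator)
#' @export
simulate_phenotypes <- function(rils, arch, mode = c("indicator", "raw"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(rils, "ril_genotypes")) stop_config("`rils` must be ril_genotypes")
  if (!inherits(arch, "trait_architecture"))
    stop_config("`arch` must be a trait_architecture")
  n <- length(rils$line_ids)
  n_env <- arch$n_env
  n_rep <- arch$n_rep

  if (nrow(arch$qtl) > 0) {
    s <- locus_scores(rils, arch$qtl$gene_id)
    G <- drop(s %*% (arch$qtl$effect / 2))
    GE <- if (!is.null(arch$gei)) s %*% (arch$gei / 2) else matrix(0, n, n_env)
  } else {
    G <- rep(0, n)
    GE <- matrix(0, n, n_env)
  }
  v_g <- var(G)

  if (v_g > 1e-12) {
    if (arch$h2_main <= 0)
      stop_config("architecture has QTL variance but target h2_main = 0")
    # Deviation-coded GEI sums to zero across environments per line, so the
    # QTL variance Vg feeds both the line-main and the interaction EMS
    # estimands; solving for the line-mean denominator D so that the ANOVA
    # heritability estimators are centred on the targets gives
    # D = Vg / (h2_main - h2_poly + h2_gei), with the unmapped polygenic
    # background contributing h2_poly * D on top of the mapped QTL.
    D <- v_g / (arch$h2_main - arch$h2_poly + arch$h2_gei)
    if (arch$h2_gei > 0) {
      if (n_env < 2)
        stop_config("h2_gei > 0 requires n_env >= 2")
      # calibrate against the ANOVA estimand: the interaction mean square
      # estimates sum(GE_dc^2) / ((a-1)(n-1)) on the doubly centred GEI
      GE_dc <- sweep(GE - rowMeans(GE), 2, colMeans(GE - rowMeans(GE)))
      v_ge_raw <- sum(GE_dc^2) / ((n - 1) * (n_env - 1))
      if (v_ge_raw <= 1e-12)
        stop_config("h2_gei > 0 but architecture has no GEI effects to scale")
      target_ge <- n_env * arch$h2_gei * D
      GE <- GE * sqrt(target_ge / v_ge_raw)
      v_ge <- target_ge
    } else {
      GE[] <- 0
      v_ge <- 0
    }
    s2_eps <- n_env * n_rep * D * (1 - arch$h2_main - arch$h2_gei)
    s2_poly <- arch$h2_poly * D
  } else {
    # no mapped QTL: pure polygenic and/or noise trait at noise_scale units
    D <- arch$noise_scale
    GE[] <- 0
    v_ge <- 0
    s2_poly <- arch$h2_poly * D
    s2_eps <- n_env * n_rep * D * (1 - arch$h2_poly)
  }

  with_seed(seed, {
    if (s2_poly > 0) G <- G + rnorm(n, 0, sqrt(s2_poly))
    idx <- expand.grid(rep = seq_len(n_rep), env = seq_len(n_env),
                       line = seq_len(n))
    eps <- rnorm(nrow(idx), 0, sqrt(s2_eps))
    value <- arch$mu + G[idx$line] + GE[cbind(idx$line, idx$env)] + eps
    indicator <- data.frame(
      line = rils$line_ids[idx$line],
      env = sprintf("E%d", idx$env),
      rep = idx$rep,
      value = value,
      stringsAsFactors = FALSE
    )
    plots <- NULL
    if (mode == "raw") {
      nn <- sample(8:14, n, replace = TRUE)
      ph_ck <- pmax(rnorm(nrow(idx), 80, 5), 30)
      if (any(value <= 0))
        stop_config("raw mode requires positive latent indicators; lower noise or raise mu")
      plots <- rbind(
        data.frame(line = indicator$line, env = indicator$env,
                   rep = indicator$rep, condition = "control",
                   PH = ph_ck, NN = nn[idx$line], stringsAsFactors = FALSE),
        data.frame(line = indicator$line, env = indicator$env,
                   rep = indicator$rep, condition = "shade",
                   PH = ph_ck * value, NN = nn[idx$line],
                   stringsAsFactors = FALSE)
      )
    }
    structure(
      list(
        indicator = indicator, plots = plots,
        truth = list(
          G = setNames(G, rils$line_ids), GE = GE, mu = arch$mu,
          sigma2_g = v_g, sigma2_ge = v_ge, sigma2_eps = s2_eps,
          sigma2_poly = s2_poly,
          line_mean_var = if (v_g > 1e-12) D else D,
          n_env = n_env, n_rep = n_rep
        )
      ),
      class = "sim_phenotypes"
    )
  })
}

#' @export
print.sim_phenotypes <- function(x, ...) {
  cat(sprintf(
    "sim_phenotypes: %d plot values (%d lines x %d env x %d rep)%s\n",
    nrow(x$indicator), length(unique(x$indicator$line)),
    x$truth$n_env, x$truth$n_rep,
    if (is.null(x$plots)) "" else " + raw PH/NN records"
  ))
  invisible(x)
}

#' Back-construct pith-cell micrograph records from latent RCL values
#'
#' Builds per-line shade and control micrograph cell-length records whose
#' [compute_rcl()] output reproduces the supplied relative-cell-length
#' values exactly: each line gets control images whose pooled mean equals
#' `control_mean` and one shade image per RCL value with image mean
#' `rcl * control_mean`.
#'
#' @param rcl A data frame with columns `line` and `value` (one row per
#'   shade image, typically 5 per line).
#' @param control_mean Pooled control-image mean cell length (micrometres).
#' @param n_control_images,cells_per_image Control image layout per line.
#' @param length_sd Within-image cell-length spread (micrometres); capped
#'   at 15% of the image mean so short-celled images stay positive.
#' @param seed Integer seed, or `NULL`.
#' @return Data frame `line`, `condition`, `image_id`, `length` (one row
#'   per measured cell).
#' @export
simulate_cells <- function(rcl, control_mean = 40, n_control_images = 3,
                           cells_per_image = 30, length_sd = 5, seed = NULL) {
  stopifnot(is.data.frame(rcl), all(c("line", "value") %in% names(rcl)))
  if (any(rcl$value <= 0)) stop_config("RCL values must be positive")
  with_seed(seed, {
    out <- vector("list", 2 * nrow(rcl))
    k <- 0
    for (ln in unique(rcl$line)) {
      # control pool with exact pooled mean
      m <- n_control_images * cells_per_image
      noise <- rnorm(m, 0, min(length_sd, 0.15 * control_mean))
      lens <- control_mean + noise - mean(noise)
      k <- k + 1
      out[[k]] <- data.frame(
        line = ln, condition = "control",
        image_id = sprintf("%s_ck_img%d", ln, rep(seq_len(n_control_images),
                                                  each = cells_per_image)),
        length = lens, stringsAsFactors = FALSE
      )
      vals <- rcl$value[rcl$line == ln]
      for (i in seq_along(vals)) {
        target <- vals[i] * control_mean
        noise <- rnorm(cells_per_image, 0, min(length_sd, 0.15 * target))
        lens <- target + noise - mean(noise)
        k <- k + 1
        out[[k]] <- data.frame(
          line = ln, condition = "shade",
          image_id = sprintf("%s_s_img%d", ln, i),
          length = lens, stringsAsFactors = FALSE
        )
      }
    }
    cells <- do.call(rbind, out[seq_len(k)])
    if (any(cells$length <= 0))
      stop_config("negative cell lengths generated; reduce length_sd")
    rownames(cells) <- NULL
    cells
  })
}
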
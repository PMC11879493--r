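#' Construct a trait architecture by hand
#'
#' A trait architecture lists the QTL (gene loci) underlying a simulated
#' indicator, their effects, and the target heritability decomposition used
#' to calibrate environmental noise. An `effect` is the expected difference
#' between the two homozygous parental classes (allele substitution
#' contrast), so deviation-coded allele effects are `+effect/2` (P1 class)
#' and `-effect/2` (P2 class).
#'
#' @param gene_id Character vector of QTL gene ids (must exist in the map
#'   used downstream); may be empty for a pure-noise trait.
#' @param effect Numeric vector of homozygous-contrast effects, same length.
#' @param gei Optional matrix (QTL x environments) of genotype-by-environment
#'   contrast effects; rows are centred across environments (deviation
#'   coding). `NULL` for no GEI.
#' @param mu Intercept (population mean) in trait units.
#' @param h2_main,h2_gei Target heritability shares on the line-mean scale,
#'   `h2_main + h2_gei < 1`.
#' @param h2_poly Share of `h2_main` carried by an unmapped polygenic
#'   background (an i.i.d. normal line effect not tied to any genotyped
#'   locus), `0 <= h2_poly < h2_main` when QTL are present. Mirrors the
#'   polygene-remainder concept: mapped loci explain `h2_main - h2_poly`.
#' @param n_env,n_rep Number of environments and replications per
#'   environment of the phenotyping design.
#' @param noise_scale Phenotypic variance scale used only when the QTL part
#'   is empty or null (pure-noise traits), in trait-units squared.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(gene_id, effect, gei = NULL, mu = 1.6,
                               h2_main = 0.67, h2_gei = 0, n_env = 3,
                               n_rep = 3, noise_scale = 1, h2_poly = 0) {
  if (length(gene_id) != length(effect))
    stop_config("gene_id and effect must have equal length")
  if (!all(is.finite(effect))) stop_config("effects must be finite")
  check_number(h2_main, "h2_main", min = 0, max = 1)
  check_number(h2_gei, "h2_gei", min = 0, max = 1)
  if (h2_main + h2_gei >= 1)
    stop_config("h2_main + h2_gei must be < 1")
  check_number(h2_poly, "h2_poly", min = 0, max = 1)
  if (length(gene_id) > 0 && h2_poly >= h2_main && h2_poly > 0)
    stop_config("h2_poly must be < h2_main when QTL are present")
  check_number(n_env, "n_env", min = 1, integer = TRUE)
  check_number(n_rep, "n_rep", min = 1, integer = TRUE)
  if (!is.null(gei)) {
    gei <- as.matrix(gei)
    if (nrow(gei) != length(gene_id) || ncol(gei) != n_env)
      stop_config("gei must be a (n_qtl x n_env) matrix")
    gei <- gei - rowMeans(gei) # deviation coding across environments
  }
  structure(
    list(
      qtl = data.frame(gene_id = as.character(gene_id), effect = effect,
                       stringsAsFactors = FALSE),
      gei = gei, mu = mu, h2_main = h2_main, h2_gei = h2_gei,
      h2_poly = h2_poly, n_env = n_env, n_rep = n_rep,
      noise_scale = noise_scale
    ),
    class = "trait_architecture"
  )
}

#' Draw a random trait architecture from a genetic map
#'
#' Samples `n_qtl` gene loci without replacement and draws their main and
#' GEI effects from normal distributions; GEI effects are centred across
#' environments per QTL.
#'
#' @param map A [make_map()] `genetic_map`.
#' @param n_qtl Number of QTL (0 allowed: pure-noise trait).
#' @param effect_sd Standard deviation of main effects (trait units).
#' @param gei_sd Standard deviation of GEI effects before centring; 0 means
#'   no GEI.
#' @inheritParams trait_architecture
#' @param seed Integer seed, or `NULL`.
#' @return A `trait_architecture`.
#' @examples
#' map <- make_map(4, 10, 120, 2, seed = 1)
#' arch <- assign_architecture(map, 5, 0.1, 0.05, 0.67, 0.18, seed = 2)
#' arch$qtl
#' @export
assign_architecture <- function(map, n_qtl, effect_sd = 0.1, gei_sd = 0,
                                h2_main = 0.67, h2_gei = 0, n_env = 3,
                                n_rep = 3, seed = NULL, mu = 1.6) {
  if (!inherits(map, "genetic_map")) stop_config("`map` must be a genetic_map")
  check_number(n_qtl, "n_qtl", min = 0, integer = TRUE)
  if (n_qtl > nrow(map$loci))
    stop_config("n_qtl (%d) exceeds number of loci (%d)", n_qtl, nrow(map$loci))
  with_seed(seed, {
    ids <- if (n_qtl > 0) sample(map$loci$gene_id, n_qtl) else character(0)
    eff <- rnorm(n_qtl, 0, effect_sd)
    gei <- NULL
    if (gei_sd > 0 && n_qtl > 0) {
      gei <- matrix(rnorm(n_qtl * n_env, 0, gei_sd), n_qtl, n_env)
    } else if (n_qtl > 0) {
      gei <- matrix(0, n_qtl, n_env)
    }
    trait_architecture(ids, eff, gei = gei, mu = mu, h2_main = h2_main,
                       h2_gei = h2_gei, n_env = n_env, n_rep = n_rep)
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "trait_architecture: %d QTL, target h2 = %.2f main + %.2f GEI, %d env x %d rep\n",
    nrow(x$qtl), x$h2_main, x$h2_gei, x$n_env, x$n_rep
  ))
  invisible(x)
}
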
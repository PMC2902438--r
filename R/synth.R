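# Synthetic expression data with planted co-expression modules and monotone
# phenotype trends, plus reproducible random graphs. This is the validation
# substrate for the whole pipeline: every planted module is a ground-truth
# co-expression clique whose overall expression rises (or falls) with the
# ordered phenotype.

#' Specification of a synthetic co-expression dataset
#'
#' Defaults describe the standard validation scenario: 5 planted modules of
#' 12 genes with within-module correlation 0.9 and monotone trends of +/-0.5
#' latent units per category step (three rising, two falling), 2,000
#' background genes, and 3 ordered categories with 31/113/136 samples — the
#' grade distribution typical of a mid-size breast tumor cohort.
#'
#' @param n_background Number of background (noise) genes.
#' @param module_sizes Integer vector of planted module sizes (each >= 2).
#' @param rho Within-module correlation in (0, 1), exact in expectation when
#'   `delta = 0` and `noise_sd = 1`.
#' @param n_per_category Samples per ordered category (>= 1 each).
#' @param delta Trend effect per category step on each module's shared latent
#'   factor, recycled over modules; 0 = null module, negative = decreasing.
#' @param noise_sd Standard deviation of gene-specific noise.
#' @param seed RNG seed; a fixed seed makes the dataset bit-reproducible.
#' @return Object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_background = 2000L,
                            module_sizes = rep(12L, 5L),
                            rho = 0.9,
                            n_per_category = c(31L, 113L, 136L),
                            delta = c(0.5, 0.5, 0.5, -0.5, -0.5),
                            noise_sd = 1,
                            seed = 1L) {
  n_background <- as.integer(n_background)
  module_sizes <- as.integer(module_sizes)
  n_per_category <- as.integer(n_per_category)
  stopifnot(n_background >= 0L,
            all(module_sizes >= 2L),
            length(rho) == 1L, rho > 0, rho < 1,
            length(n_per_category) >= 1L, all(n_per_category >= 1L),
            length(delta) >= 1L,
            length(noise_sd) == 1L, noise_sd > 0,
            length(seed) == 1L)
  delta <- rep_len(as.numeric(delta), length(module_sizes))
  structure(
    list(n_background = n_background, module_sizes = module_sizes,
         rho = rho, n_per_category = n_per_category, delta = delta,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "Simulation spec: %d module(s) (sizes %s, rho = %g), %d background genes,\n  categories of %s samples, delta = %s, noise sd = %g, seed = %d\n",
    length(x$module_sizes), paste(x$module_sizes, collapse = "/"), x$rho,
    x$n_background, paste(x$n_per_category, collapse = "/"),
    paste(x$delta, collapse = "/"), x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate expression data with planted trend-bearing modules
#'
#' Latent-factor construction: gene g of module m in sample s of category
#' rank c gets `sqrt(rho) * f_m(s) + sqrt(1 - rho) * eps_g(s)`, where the
#' shared factor `f_m(s) ~ N(delta_m * c, 1)` carries the monotone trend
#' (category ranks 0, 1, 2, ...) and `eps_g(s) ~ N(0, noise_sd^2)` is
#' gene-specific. Background genes are pure noise. Rows are then
#' z-standardized, so within-module pairwise correlation is `rho` in
#' expectation when `delta = 0` and `noise_sd = 1`, and the module overall
#' expression inherits the monotone trend.
#'
#' @param spec A [simulation_spec()].
#' @return List of class `"synthetic_dataset"`:
#'   \describe{
#'     \item{expression}{standardized gene x sample matrix;}
#'     \item{phenotype}{named ordered factor of category labels
#'       (`"1" < "2" < ...`);}
#'     \item{truth}{list with `module_genes` (named list), `delta` (named),
#'       `direction` (named: `"up"`, `"down"`, `"null"`), `rho`, and
#'       `background_genes`.}
#'   }
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  npc <- spec$n_per_category
  N <- sum(npc)
  rank <- rep(seq_along(npc) - 1L, npc)
  samples <- sprintf("S%03d", seq_len(N))
  pheno <- factor(rep(as.character(seq_along(npc)), npc),
                  levels = as.character(seq_along(npc)), ordered = TRUE)
  names(pheno) <- samples
  nmod <- length(spec$module_sizes)
  blocks <- vector("list", nmod + 1L)
  module_genes <- stats::setNames(vector("list", nmod),
                                  sprintf("planted_%d", seq_len(nmod)))
  for (m in seq_len(nmod)) {
    size <- spec$module_sizes[m]
    f <- stats::rnorm(N) + spec$delta[m] * rank
    eps <- matrix(stats::rnorm(size * N, sd = spec$noise_sd), size, N)
    block <- sqrt(spec$rho) * matrix(f, size, N, byrow = TRUE) +
      sqrt(1 - spec$rho) * eps
    rownames(block) <- sprintf("M%02dG%02d", m, seq_len(size))
    module_genes[[m]] <- rownames(block)
    blocks[[m]] <- block
  }
  if (spec$n_background > 0L) {
    bg <- matrix(stats::rnorm(spec$n_background * N, sd = spec$noise_sd),
                 spec$n_background, N)
    rownames(bg) <- sprintf("BG%04d", seq_len(spec$n_background))
    blocks[[nmod + 1L]] <- bg
  }
  raw <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  colnames(raw) <- samples
  attr(raw, "standardized") <- FALSE
  expr <- standardize_expression(raw)
  delta <- stats::setNames(spec$delta, names(module_genes))
  direction <- ifelse(delta > 0, "up", ifelse(delta < 0, "down", "null"))
  structure(
    list(expression = expr,
         phenotype = pheno,
         truth = list(module_genes = module_genes, delta = delta,
                      direction = direction, rho = spec$rho,
                      background_genes = if (spec$n_background > 0L)
                        rownames(blocks[[nmod + 1L]]) else character(0))),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d genes x %d samples, %d planted module(s)\n",
    nrow(x$expression), ncol(x$expression), length(x$truth$module_genes)))
  invisible(x)
}

#' Reproducible Erdos-Renyi random graph
#'
#' @param n Number of vertices.
#' @param p Edge probability in \[0, 1\].
#' @param seed Optional RNG seed for reproducibility.
#' @return Undirected igraph G(n, p) with vertex names `v001, v002, ...`.
#' @export
random_graph <- function(n, p, seed = NULL) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  if (n > 0L) {
    igraph::V(g)$name <- sprintf(paste0("v%0", max(3L, nchar(n)), "d"),
                                 seq_len(n))
  }
  g
}
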
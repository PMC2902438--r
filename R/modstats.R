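# Module-level phenotype screening: module overall expression,
# Jonckheere-Terpstra trend test, BH-FDR across the module family, and the
# cross-cohort reproducibility metric.

#' Overall expression of a module
#'
#' Per-sample arithmetic mean of the standardized expression of the module's
#' genes. Genes absent from the matrix (e.g. not on the validation platform)
#' are skipped and counted.
#'
#' @param expr Standardized gene x sample matrix.
#' @param genes Character vector of module gene names.
#' @return Named numeric vector (one value per sample) with attributes
#'   `n_genes` (genes used) and `n_missing` (genes not found).
#' @export
module_expression <- function(expr, genes) {
  .check_expression(expr)
  if (!is_standardized(expr)) stop("expression matrix must be standardized")
  genes <- unique(as.character(genes))
  present <- intersect(genes, rownames(expr))
  if (!length(present))
    stop("none of the module genes are present in the expression matrix")
  x <- colMeans(expr[present, , drop = FALSE])
  attr(x, "n_genes") <- length(present)
  attr(x, "n_missing") <- length(genes) - length(present)
  x
}

# W statistic: sum over ordered category pairs i < j of the number of
# observation pairs with X_i < X_j, ties counted 0.5.
.jt_W <- function(groups) {
  s <- length(groups)
  W <- 0
  for (i in seq_len(s - 1L)) {
    xi <- groups[[i]]
    for (j in (i + 1L):s) {
      xj <- groups[[j]]
      W <- W + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
  }
  W
}

# Enumerate all distinct assignments of the pooled values to groups of the
# given sizes and return the W of each (exact permutation null).
.jt_perm_W <- function(values, sizes) {
  out <- numeric(0)
  recurse <- function(remaining_idx, gi, acc) {
    if (gi == length(sizes)) {
      acc[[gi]] <- values[remaining_idx]
      out[length(out) + 1L] <<- .jt_W(acc)
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining_idx, sizes[gi], simplify = FALSE)
    for (p in picks) {
      acc[[gi]] <- values[p]
      recurse(setdiff(remaining_idx, p), gi + 1L, acc)
    }
    invisible(NULL)
  }
  recurse(seq_along(values), 1L, vector("list", length(sizes)))
  out
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a response across ordered categories. The
#' statistic `W` sums, over all ordered category pairs i < j, the number of
#' observation pairs with the category-i value below the category-j value
#' (ties counted 0.5). Under the null (no trend), for N observations in
#' groups of sizes n_i,
#' `E(W) = (N^2 - sum(n_i^2)) / 4` and
#' `Var(W) = (N^2 (2N + 3) - sum(n_i^2 (2 n_i + 3))) / 72`,
#' and `z = (W - E(W)) / sqrt(Var(W))` is approximately standard normal.
#' The variance is the no-tie form; for small samples (or heavy ties) the
#' exact permutation null is available.
#'
#' @param x Numeric response values (e.g. module overall expression).
#' @param g Ordered categories, one per value: an ordered factor or anything
#'   coercible to one (factor level order = category order). Samples with
#'   missing category or value are dropped.
#' @param alternative `"two.sided"` (default), `"increasing"`, or
#'   `"decreasing"`.
#' @param exact Also compute the exact permutation p-value by enumerating all
#'   distinct group assignments (feasible for small N; refuses families
#'   beyond 500000 arrangements).
#' @return Object of class `"jt_test"`: list with `W`, `mean0`, `var0`, `z`,
#'   `p.value`, `alternative`, `group_sizes`, `n`, and (when `exact`)
#'   `p.exact`.
#' @examples
#' jt_test(c(1, 2, 3, 4, 5, 6), gl(3, 2, ordered = TRUE))
#' @export
jt_test <- function(x, g, alternative = c("two.sided", "increasing", "decreasing"),
                    exact = FALSE) {
  alternative <- match.arg(alternative)
  if (!is.factor(g)) g <- factor(g, ordered = TRUE)
  stopifnot(length(x) == length(g))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L)
    stop("need at least 2 non-empty ordered categories")
  groups <- split(x, g)
  n_i <- lengths(groups)
  N <- sum(n_i)
  if (N < 3L) stop("need at least 3 observations")
  W <- .jt_W(groups)
  mean0 <- (N^2 - sum(n_i^2)) / 4
  var0 <- (N^2 * (2 * N + 3) - sum(n_i^2 * (2 * n_i + 3))) / 72
  z <- (W - mean0) / sqrt(var0)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    increasing = stats::pnorm(z, lower.tail = FALSE),
    decreasing = stats::pnorm(z)
  )
  p <- min(1, p)
  out <- list(W = W, mean0 = mean0, var0 = var0, z = z, p.value = p,
              alternative = alternative, group_sizes = n_i, n = N)
  if (exact) {
    n_arr <- exp(lgamma(N + 1) - sum(lgamma(n_i + 1)))
    if (n_arr > 5e5)
      stop(sprintf("exact permutation infeasible: %.3g arrangements", n_arr))
    Wp <- .jt_perm_W(x, n_i)
    p_ge <- mean(Wp >= W - 1e-9)
    p_le <- mean(Wp <= W + 1e-9)
    out$p.exact <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      increasing = p_ge,
      decreasing = p_le
    )
    out$n_arrangements <- length(Wp)
  }
  structure(out, class = "jt_test")
}

#' @export
print.jt_test <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test\n")
  cat(sprintf("  groups (ordered): %s\n",
              paste(x$group_sizes, collapse = ", ")))
  cat(sprintf("  W = %g, E0 = %g, Var0 = %g, z = %.4f\n",
              x$W, x$mean0, x$var0, x$z))
  cat(sprintf("  %s p-value (normal approx.) = %.4g\n", x$alternative,
              x$p.value))
  if (!is.null(x$p.exact))
    cat(sprintf("  exact permutation p-value = %.4g (%d arrangements)\n",
                x$p.exact, x$n_arrangements))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values (wraps `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Screen modules for a monotone phenotype trend
#'
#' Runs [jt_test()] on the overall expression of each module against an
#' ordered phenotype, adjusts p-values across the whole module family with
#' [bh_fdr()], and flags modules at the FDR cut. Modules with no gene on the
#' platform are reported as untestable and excluded from the FDR family.
#'
#' @param expr Standardized gene x sample matrix.
#' @param modules Named list of gene sets, or an `"ice_result"`/`"ice_fit"`
#'   (expanded modules are used).
#' @param phenotype Ordered categories per sample: named vector/factor
#'   (matched to `colnames(expr)` by name) or unnamed, aligned to columns.
#'   Missing categories drop the sample from every test.
#' @param fdr_cutoff Significance cut on the FDR (default 0.01).
#' @return Data frame with one row per module: `module`, `n_genes`,
#'   `n_missing`, `W`, `z`, `p`, `fdr`, `direction` (`"up"`/`"down"`),
#'   `significant`, `status` (`"tested"`/`"untestable"`), plus attribute
#'   `fdr_cutoff`.
#' @export
screen_modules <- function(expr, modules, phenotype, fdr_cutoff = 0.01) {
  if (inherits(modules, c("ice_result", "ice_fit")))
    modules <- module_genes(modules)
  stopifnot(is.list(modules), length(modules) >= 1L)
  if (is.null(names(modules)) || anyDuplicated(names(modules)))
    stop("modules must be uniquely named")
  if (!is.factor(phenotype)) phenotype <- factor(phenotype, ordered = TRUE)
  if (!is.null(names(phenotype))) {
    miss <- setdiff(colnames(expr), names(phenotype))
    if (length(miss))
      stop(sprintf("phenotype missing for %d sample(s)", length(miss)))
    phenotype <- phenotype[colnames(expr)]
  } else if (length(phenotype) != ncol(expr)) {
    stop("unnamed phenotype must have one entry per sample")
  }
  rows <- lapply(names(modules), function(nm) {
    res <- tryCatch({
      me <- module_expression(expr, modules[[nm]])
      jt <- jt_test(me, phenotype)
      data.frame(module = nm,
                 n_genes = attr(me, "n_genes"),
                 n_missing = attr(me, "n_missing"),
                 W = jt$W, z = jt$z, p = jt$p.value,
                 status = "tested", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(module = nm, n_genes = 0L,
                 n_missing = length(modules[[nm]]),
                 W = NA_real_, z = NA_real_, p = NA_real_,
                 status = "untestable", stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- out$status == "tested"
  out$fdr[tested] <- bh_fdr(out$p[tested])
  out$direction <- ifelse(is.na(out$z), NA_character_,
                          ifelse(out$z >= 0, "up", "down"))
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cutoff
  attr(out, "fdr_cutoff") <- fdr_cutoff
  out
}

#' Reproducibility of a biomarker set across cohorts
#'
#' The percentage of biomarkers significant in a discovery cohort that stay
#' significant in an independent validation cohort.
#'
#' @param discovery Either the count of discovery-significant biomarkers or a
#'   logical vector of discovery flags.
#' @param validation Either the count of those that validate or a logical
#'   vector of validation flags. When both arguments are equal-length
#'   logical vectors, validation flags are read only at discovery-significant
#'   positions.
#' @return Object of class `"reproducibility"`: list with `n_discovery`,
#'   `n_validation`, `percentage` (rounded to 2 decimals).
#' @examples
#' reproducibility(19, 17)   # 89.47
#' @export
reproducibility <- function(discovery, validation) {
  as_count <- function(v) {
    stopifnot(length(v) == 1L, is.numeric(v), v >= 0, v == round(v))
    as.integer(v)
  }
  if (is.logical(discovery)) {
    n_disc <- sum(discovery)
    if (is.logical(validation)) {
      if (length(validation) == length(discovery)) {
        n_val <- sum(validation & discovery)
      } else if (length(validation) == n_disc) {
        n_val <- sum(validation)
      } else {
        stop("validation flags must align with discovery flags or with the discovery-significant subset")
      }
    } else {
      n_val <- as_count(validation)
    }
  } else {
    n_disc <- as_count(discovery)
    n_val <- if (is.logical(validation)) sum(validation) else as_count(validation)
  }
  if (n_disc == 0L)
    stop("reproducibility undefined: no discovery-significant biomarker")
  if (n_val > n_disc)
    stop("validation count exceeds discovery count")
  structure(
    list(n_discovery = n_disc, n_validation = n_val,
         percentage = round(100 * n_val / n_disc, 2)),
    class = "reproducibility"
  )
}

#' @export
print.reproducibility <- function(x, ...) {
  cat(sprintf("%d of %d biomarkers reproduced (%.2f%%)\n",
              x$n_validation, x$n_discovery, x$percentage))
  invisible(x)
}
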
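#' Haploid genotype matrix with missing-data bookkeeping
#'
#' The central container of the package: an integer matrix of haploid calls
#' (rows = samples, columns = variant sites) coded `0` = ancestral,
#' `1` = derived, `NA` = missing (outside the sample's callable mask, or an
#' unresolvable call). Alongside the variant calls it tracks the pieces of
#' information the dating engine needs about the *invariant* part of the
#' chromosome: the size `L` of the callable site universe, the per-sample
#' callable totals `L_s`, and the pairwise shared-callable counts used as
#' pairwise-deletion distance denominators.
#'
#' @param calls integer matrix, samples x sites, values in \{0, 1, NA\};
#'   rownames are sample ids.
#' @param positions integer vector of 1-based site coordinates (one per
#'   column), strictly increasing.
#' @param L total number of callable sites in the analysis universe
#'   (variant + invariant). Defaults to `ncol(calls)`, i.e. the matrix *is*
#'   the universe — the right default for small hand-built examples.
#' @param L_s named numeric vector of per-sample callable site counts
#'   (within the universe). Defaults to `L` minus the sample's missing calls,
#'   which is exact when the matrix is the universe.
#' @param shared_callable optional samples x samples matrix of mutually
#'   callable site counts. Defaults to the number of sites non-missing in
#'   both samples plus the shared invariant remainder `L - ncol(calls)`
#'   scaled by nothing (exact when the matrix is the universe; for simulated
#'   or mask-backed data supply the exact/derived matrix).
#' @param panel optional tibble of sample metadata with at least a
#'   `sample_id` column (see [read_panel()]).
#' @param masks optional named list of per-sample callable-interval data
#'   frames (`start`, `end`, 0-based half-open) as read from BED.
#' @param log named list of ingestion counters (dropped records etc.).
#'
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, positions = seq_len(ncol(calls)), L = ncol(calls),
                        L_s = NULL, shared_callable = NULL, panel = NULL,
                        masks = NULL, log = list()) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("`calls` must have sample ids as rownames")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids in `calls`")
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("calls must be 0 (ancestral), 1 (derived) or NA (missing)")
  positions <- as.integer(positions)
  if (length(positions) != ncol(calls)) stop("one position per site required")
  if (is.unsorted(positions, strictly = TRUE)) {
    o <- order(positions)
    positions <- positions[o]
    calls <- calls[, o, drop = FALSE]
  }
  if (L < ncol(calls)) stop("universe size L smaller than the number of variant sites")
  obs <- !is.na(calls)
  if (is.null(L_s)) L_s <- stats::setNames(L - rowSums(!obs), rownames(calls))
  L_s <- L_s[rownames(calls)]
  if (any(is.na(L_s))) stop("L_s must name every sample")
  if (is.null(shared_callable)) {
    m <- obs * 1
    shared_callable <- m %*% t(m) + (L - ncol(calls))
  }
  if (!is.null(rownames(shared_callable))) {
    shared_callable <- shared_callable[rownames(calls), rownames(calls), drop = FALSE]
  }
  dimnames(shared_callable) <- list(rownames(calls), rownames(calls))
  colnames(calls) <- positions
  structure(
    list(calls = calls, positions = positions, L = L, L_s = L_s,
         shared_callable = shared_callable, panel = panel, masks = masks,
         log = log),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variant sites (universe L = %s)\n",
              nrow(x$calls), ncol(x$calls), format(x$L, big.mark = ",")))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%; per-sample callable L_s in [%s, %s]\n",
              100 * miss, format(min(x$L_s), big.mark = ","),
              format(max(x$L_s), big.mark = ",")))
  if (length(x$log)) {
    cat("  log:", paste(names(x$log), unlist(x$log), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

sample_ids <- function(gm) rownames(gm$calls)

#' Drop sites with no observed derived call
#'
#' Enforces the variant-sites-only invariant: every retained column carries at
#' least one non-missing derived call. Returns the filtered matrix with a
#' `dropped_invariant` counter appended to the log.
#' @param gm a [geno_matrix()].
#' @return a `geno_matrix`.
#' @export
drop_uninformative_sites <- function(gm) {
  keep <- colSums(gm$calls == 1L, na.rm = TRUE) > 0
  if (all(keep)) {
    gm$log$dropped_invariant <- (gm$log$dropped_invariant %||% 0L)
    return(gm)
  }
  gm$log$dropped_invariant <- (gm$log$dropped_invariant %||% 0L) + sum(!keep)
  gm$calls <- gm$calls[, keep, drop = FALSE]
  gm$positions <- gm$positions[keep]
  gm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
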
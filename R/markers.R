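#' Read a haplogroup marker table
#'
#' Expected TSV columns: `marker` (e.g. M347), `position` (1-based),
#' `ancestral`, `derived` (alleles, informational), `haplogroup` (the label a
#' derived call implies, e.g. "C-M347"), `parent` (the parent haplogroup
#' label, empty at the top level). The parent links must form a forest, so a
#' derived call at a nested marker implies derived state at its ancestors
#' (e.g. C-M347 implies C-M130).
#'
#' @param path TSV file.
#' @return a tibble.
#' @export
read_marker_table <- function(path) {
  mt <- tibble::as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE,
    colClasses = c(position = "integer"), fill = TRUE,
    na.strings = character(0)))
  validate_marker_table(mt)
}

validate_marker_table <- function(mt) {
  need <- c("marker", "position", "haplogroup", "parent")
  if (!all(need %in% names(mt))) {
    stop("marker table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(mt$position)) stop("marker positions must be unique")
  if (anyDuplicated(mt$haplogroup)) stop("haplogroup labels must be unique")
  # parent links must form a forest over the table's haplogroups
  known <- c("", mt$haplogroup)
  if (!all(mt$parent %in% known)) {
    stop("unknown parent haplogroup(s): ",
         paste(setdiff(mt$parent, known), collapse = ", "))
  }
  for (h in mt$haplogroup) {
    seen <- character(0)
    cur <- h
    while (nzchar(cur)) {
      if (cur %in% seen) stop("marker hierarchy contains a cycle at ", cur)
      seen <- c(seen, cur)
      cur <- mt$parent[match(cur, mt$haplogroup)]
    }
  }
  mt
}

marker_depth <- function(mt, hg) {
  d <- 0L
  cur <- hg
  while (nzchar(cur)) {
    cur <- mt$parent[match(cur, mt$haplogroup)]
    d <- d + 1L
  }
  d
}

marker_ancestors <- function(mt, hg) {
  out <- character(0)
  cur <- hg
  while (nzchar(cur)) {
    out <- c(out, cur)
    cur <- mt$parent[match(cur, mt$haplogroup)]
  }
  out
}

#' Assign a haplogroup from marker calls
#'
#' The deepest marker with a derived call wins; every other derived marker
#' must lie on that marker's ancestral chain (missing intermediate markers
#' are tolerated), otherwise the derived calls sit on incompatible branches
#' and an error is raised, since that signals a data problem. With no derived
#' marker call the sample is "unassigned".
#'
#' @param calls named vector of marker calls (0 ancestral, 1 derived, NA
#'   missing), named by position or by marker name.
#' @param marker_table a tibble from [read_marker_table()].
#' @return the winning haplogroup label, e.g. "C-M347".
#' @export
assign_haplogroup <- function(calls, marker_table) {
  mt <- validate_marker_table(marker_table)
  key <- names(calls)
  idx <- match(key, as.character(mt$position))
  idx2 <- match(key, mt$marker)
  idx[is.na(idx)] <- idx2[is.na(idx)]
  ok <- !is.na(idx)
  derived <- mt$haplogroup[idx[ok]][!is.na(calls[ok]) & calls[ok] == 1L]
  if (!length(derived)) return("unassigned")
  depths <- vapply(derived, marker_depth, integer(1), mt = mt)
  winner <- derived[order(-depths, derived)][1]
  chain <- marker_ancestors(mt, winner)
  off <- setdiff(derived, chain)
  if (length(off)) {
    stop("conflicting derived marker calls on incompatible branches: ",
         winner, " vs ", paste(off, collapse = ", "))
  }
  winner
}

#' Assign haplogroups for every sample in a genotype matrix
#'
#' Marker positions absent from the matrix are treated as missing for all
#' samples; positions present are read off each sample's (masked) calls.
#'
#' @param gm a [geno_matrix()].
#' @param marker_table a tibble from [read_marker_table()].
#' @return a tibble with `sample_id`, `haplogroup`.
#' @export
assign_haplogroups <- function(gm, marker_table) {
  mt <- validate_marker_table(marker_table)
  col <- match(mt$position, gm$positions)
  labs <- vapply(sample_ids(gm), function(s) {
    calls <- rep(NA_integer_, nrow(mt))
    calls[!is.na(col)] <- gm$calls[s, col[!is.na(col)]]
    names(calls) <- mt$marker
    assign_haplogroup(calls, mt)
  }, character(1))
  tibble::tibble(sample_id = sample_ids(gm), haplogroup = unname(labs))
}
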
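#' Write a simulated dataset to standard file formats
#'
#' Emits a VCF 4.2 (single contig "Y", biallelic SNVs, REF = ancestral,
#' ALT = derived, `AA` INFO tag), one callable-mask BED per sample (0-based
#' half-open), the sample panel TSV, the true tree as Newick (branch lengths
#' in years) and a JSON sidecar with per-edge mutation counts and positions.
#' Requires the exact-mask simulation route (`L <= mask_limit`), because BED
#' masks cover invariant sites too.
#'
#' @param sim a [simulate_snv_dataset()] result.
#' @param dir output directory (created if needed).
#' @param diploid emit genotypes as homozygous-diploid ("0/0"/"1/1") instead
#'   of haploid ("0"/"1"); both dialects occur in public Y-chromosome VCFs.
#' @return `dir`, invisibly; files: `variants.vcf`, `mask_<sample>.bed`,
#'   `panel.tsv`, `truth.nwk`, `truth.json`.
#' @export
write_sim_dataset <- function(sim, dir, diploid = FALSE) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (is.null(sim$masks)) {
    stop("exact per-site masks were not materialised (L > mask_limit); ",
         "BED output needs them")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$matrix_full
  write_vcf(gm, file.path(dir, "variants.vcf"), diploid = diploid)
  for (s in sample_ids(gm)) {
    write_bed_mask(sim$masks[s, ], file.path(dir, sprintf("mask_%s.bed", s)))
  }
  utils::write.table(sim$panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$tree, file.path(dir, "truth.nwk"))
  jsonlite::write_json(
    list(mu = sim$truth$mu, L = sim$truth$L,
         edge_counts = sim$truth$edge_counts,
         edge_sites = sim$truth$edge_sites),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a genotype matrix as VCF text
#'
#' @param gm a [geno_matrix()].
#' @param path output file.
#' @param diploid homozygous-diploid genotype dialect instead of haploid.
#' @export
write_vcf <- function(gm, path, diploid = FALSE) {
  ids <- sample_ids(gm)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=Y,length=%d>", as.integer(gm$L)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  M <- ncol(gm$calls)
  if (M == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt <- ifelse(is.na(gm$calls), ".", as.character(gm$calls))
  if (diploid) gt <- ifelse(gt == ".", "./.", paste(gt, gt, sep = "/"))
  gt <- matrix(gt, nrow = nrow(gm$calls))            # S x M
  rec <- paste(
    "Y", gm$positions, ".", "A", "G", ".", ".", "AA=A", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# logical callable vector (length L) -> BED intervals (0-based half-open)
write_bed_mask <- function(callable, path) {
  r <- rle(as.logical(callable))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  df <- data.frame(chrom = "Y", start = starts[keep], end = ends[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample callable mask from BED
#'
#' @param path BED file (first three columns used; 0-based half-open).
#' @return data frame with `start`, `end` (0-based half-open), sorted.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "numeric", "numeric"))
  df <- df[order(df$start), c("start", "end")]
  rownames(df) <- NULL
  df
}

#' Read a sample panel TSV
#'
#' Expected columns: `sample_id`, `population`, `coverage_class`
#' (high/low), optional `haplogroup_truth`.
#' @param path TSV file.
#' @return a tibble.
#' @export
read_panel <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = "character"))
}

bed_total <- function(bed) sum(bed$end - bed$start)

# 1-based positions inside a 0-based half-open interval set
bed_contains <- function(bed, pos) {
  if (nrow(bed) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos - 1L, bed$start)   # 1-based pos -> 0-based coord
  idx > 0L & (pos - 1L) < bed$end[pmax(idx, 1L)]
}

#' Read haploid genotypes from VCF with callable masks into a genotype matrix
#'
#' Retains biallelic SNVs only (indels, multiallelic and symbolic records are
#' dropped and counted in the log). Haploid ("0"/"1") and homozygous-diploid
#' ("0/0", "1|1") calls are accepted; heterozygous diploid calls on a haploid
#' chromosome are treated as missing with a logged count. The ancestral state
#' is REF unless an `AA` INFO tag names the ALT allele, in which case the
#' site's coding is flipped. Genotypes at sites outside a sample's mask are
#' set to missing, and sites left with no observed derived call are dropped.
#'
#' @param vcf path to a VCF file.
#' @param masks named list (sample -> BED path or data frame from
#'   [read_bed()]). Samples without an entry are taken as fully callable over
#'   `1:L`.
#' @param panel a panel tibble ([read_panel()]) or TSV path covering every
#'   VCF sample.
#' @param L size of the callable site universe (defaults to the contig length
#'   declared in the VCF header, if any, else the largest variant position).
#' @param filters list of optional site filters; `min_qual` drops records
#'   with QUAL below the threshold (off by default).
#' @return a [geno_matrix()] with ingestion counters in `$log`.
#' @export
read_genotypes <- function(vcf, masks = NULL, panel = NULL, L = NULL,
                           filters = list()) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(fix) > 0 && length(unique(fix[, "CHROM"])) > 1L) {
    stop("multiple contigs in VCF; expected a single (Y) contig")
  }
  if (is.null(L)) {
    ctg <- grep("^##contig=", v@meta, value = TRUE)
    len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
    L <- if (length(len) && !is.na(len[1])) len[1] else {
      if (nrow(fix)) max(as.numeric(fix[, "POS"])) else 1
    }
  }
  ids <- colnames(v@gt)[-1]
  if (is.character(panel) && length(panel) == 1L) panel <- read_panel(panel)
  if (!is.null(panel)) {
    missing_p <- setdiff(ids, panel$sample_id)
    if (length(missing_p)) {
      stop("samples in VCF absent from panel: ", paste(missing_p, collapse = ", "))
    }
  }

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- !is.na(alt) & grepl(",", alt)
  log <- list(dropped_multiallelic = sum(multi),
              dropped_non_snv = sum(!snv & !multi))
  keep <- snv & !multi
  if (!is.null(filters$min_qual)) {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    low <- keep & (is.na(qual) | qual < filters$min_qual)
    log$dropped_low_qual <- sum(low)
    keep <- keep & !low
  }

  pos <- as.integer(fix[keep, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = length(pos),
                  dimnames = list(ids, NULL))
  clean <- gsub("\\|", "/", ifelse(is.na(gt), ".", gt))
  het <- 0L
  for (s in seq_along(ids)) {
    g <- clean[, s]
    x <- rep(NA_integer_, length(g))
    x[g %in% c("0", "0/0")] <- 0L
    x[g %in% c("1", "1/1")] <- 1L
    is_het <- g %in% c("0/1", "1/0")
    het <- het + sum(is_het)
    calls[s, ] <- x
  }
  log$het_set_missing <- het

  # ancestral = REF unless AA INFO names the ALT allele
  info <- fix[keep, "INFO"]
  info[is.na(info)] <- ""
  aa <- ifelse(grepl("AA=", info), sub(".*AA=([^;]+).*", "\\1", info), NA)
  flip <- !is.na(aa) & aa == fix[keep, "ALT"]
  if (any(flip)) calls[, flip] <- 1L - calls[, flip]
  log$polarity_flipped <- sum(flip)

  # masks
  mask_list <- NULL
  L_s <- stats::setNames(rep(as.double(L), length(ids)), ids)
  if (!is.null(masks)) {
    mask_list <- lapply(ids, function(s) {
      m <- masks[[s]]
      if (is.null(m)) return(data.frame(start = 0, end = L))
      if (is.character(m)) m <- read_bed(m)
      m
    })
    names(mask_list) <- ids
    for (s in ids) {
      bed <- mask_list[[s]]
      L_s[s] <- bed_total(bed)
      if (L_s[s] == 0) {
        warning("sample ", s, " has an empty callable mask; all calls missing")
      }
      calls[s, !bed_contains(bed, pos)] <- NA_integer_
    }
    shared <- shared_callable_from_masks(mask_list)
  } else {
    obs <- (!is.na(calls)) * 1
    shared <- obs %*% t(obs) + (L - length(pos))
  }

  gm <- geno_matrix(calls, positions = pos, L = L, L_s = L_s,
                    shared_callable = shared,
                    panel = panel, masks = mask_list, log = log)
  drop_uninformative_sites(gm)
}

# exact pairwise shared-callable counts from interval masks
shared_callable_from_masks <- function(mask_list) {
  ids <- names(mask_list)
  n <- length(ids)
  shared <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared[i, j] <- shared[j, i] <-
        interval_overlap(mask_list[[i]], mask_list[[j]])
    }
  }
  shared
}

interval_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end[j] <= a$start[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start[k] < a$end[i]) {
      tot <- tot + min(a$end[i], b$end[k]) - max(a$start[i], b$start[k])
      k <- k + 1L
    }
  }
  tot
}

#' Merge disjoint cohorts sharing a coordinate system
#'
#' Takes the union of variant sites. A sample with no record at a site
#' contributed by another cohort is set to the ancestral state if the site
#' falls inside its callable mask (reference-implied call), and to missing
#' outside it — so low-coverage absence is never read as ancestral.
#'
#' @param ... two or more [geno_matrix()] objects with disjoint sample sets
#'   and equal universe size `L`.
#' @return a merged [geno_matrix()].
#' @export
merge_cohorts <- function(...) {
  gms <- list(...)
  if (length(gms) == 1L) return(gms[[1]])
  ids <- unlist(lapply(gms, sample_ids))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  Ls <- vapply(gms, function(g) g$L, numeric(1))
  if (length(unique(Ls)) != 1L) stop("cohorts disagree on universe size L")
  pos <- sort(unique(unlist(lapply(gms, function(g) g$positions))))
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = length(pos),
                  dimnames = list(ids, NULL))
  for (g in gms) {
    col <- match(g$positions, pos)
    new <- setdiff(seq_along(pos), col)
    for (s in sample_ids(g)) {
      row <- rep(NA_integer_, length(pos))
      row[col] <- g$calls[s, ]
      if (length(new)) {
        callable <- if (!is.null(g$masks)) {
          bed_contains(g$masks[[s]], pos[new])
        } else rep(TRUE, length(new))
        row[new][callable] <- 0L
      }
      calls[s, ] <- row
    }
  }
  masks <- do.call(c, lapply(gms, function(g) {
    g$masks %||% stats::setNames(
      rep(list(data.frame(start = 0, end = g$L)), nrow(g$calls)),
      sample_ids(g))
  }))
  L_s <- do.call(c, lapply(gms, function(g) g$L_s))
  shared <- shared_callable_from_masks(masks)
  panel <- do.call(rbind, lapply(gms, function(g) g$panel))
  gm <- geno_matrix(calls, positions = pos, L = Ls[1], L_s = L_s,
                    shared_callable = shared, panel = panel, masks = masks,
                    log = list())
  drop_uninformative_sites(gm)
}
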
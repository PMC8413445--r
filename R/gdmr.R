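#' Cluster sorted genomic positions by maximum gap
#'
#' Consecutive positions at most `maxgap` bp apart share a cluster id; ids
#' increase along the genome.
#'
#' @param positions Sorted bp positions (one chromosome).
#' @param maxgap Maximum within-cluster gap in bp.
#' @return Integer cluster ids, one per position.
#' @export
cluster_sites <- function(positions, maxgap) {
  if (!length(positions)) return(integer(0))
  if (is.unsorted(positions)) rlang::abort("`positions` must be sorted")
  cumsum(c(1L, as.integer(diff(positions) > maxgap)))
}

#' Find genetic DMRs from one SNP's per-site t-statistics
#'
#' Within each gap-defined cluster, maximal runs of consecutive sites whose
#' association statistic passes `|t| >= cutoff` with a common sign become
#' candidate regions; runs shorter than `min_sites` are dropped. Mixed-sign
#' runs split at sign changes.
#'
#' @param t Per-site t statistics (aligned with `positions`).
#' @param positions Sorted site positions.
#' @param p Optional per-site p-values (for the region mean).
#' @param cutoff Absolute-t threshold (default 5; 3.5 gives the liberal
#'   set).
#' @param maxgap Cluster gap in bp (default 1000).
#' @param min_sites Minimum member sites per region (default 2).
#' @param snp_id Optional index-SNP label carried into the output.
#' @param chrom Chromosome label.
#' @return Tibble of regions: chrom, start, end (1-based inclusive, member
#'   extremes), snp_id, n_sites, mean_t, mean_p, sign.
#' @export
find_gdmrs <- function(t, positions, p = NULL, cutoff = 5, maxgap = 1000,
                       min_sites = 2, snp_id = NA_character_,
                       chrom = "chrSim") {
  stopifnot(length(t) == length(positions))
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), snp_id = character(0),
                          n_sites = integer(0), mean_t = numeric(0),
                          mean_p = numeric(0), sign = character(0))
  if (!length(t)) return(empty)
  cl <- cluster_sites(positions, maxgap)
  state <- ifelse(is.na(t) | abs(t) < cutoff, 0L, sign(t))
  # run id changes when the cluster or the pass/sign state changes
  run <- cumsum(c(1L, as.integer(diff(cl) != 0 | diff(state) != 0)))
  keep <- state != 0L
  if (!any(keep)) return(empty)
  idx <- split(which(keep), run[keep])
  regions <- purrr::map(idx, function(i) {
    if (length(i) < min_sites) return(NULL)
    tibble::tibble(
      chrom = chrom, start = positions[i[1]], end = positions[i[length(i)]],
      snp_id = snp_id, n_sites = length(i), mean_t = mean(t[i]),
      mean_p = if (is.null(p)) NA_real_ else mean(p[i]),
      sign = if (t[i[1]] > 0) "+" else "-"
    )
  })
  out <- dplyr::bind_rows(regions)
  if (!nrow(out)) return(empty)
  dplyr::arrange(out, .data$start)
}

#' Find gDMRs for every SNP in a scan result
#'
#' Applies [find_gdmrs()] per SNP over its tested sites.
#'
#' @param pairs Pair tibble from [meqtl_scan()] (needs snp_id, chrom, pos,
#'   t, p).
#' @param cutoff,maxgap,min_sites As in [find_gdmrs()].
#' @return Combined region tibble sorted by (chrom, start).
#' @export
find_gdmrs_all <- function(pairs, cutoff = 5, maxgap = 1000, min_sites = 2) {
  pairs <- dplyr::arrange(pairs, .data$snp_id, .data$chrom, .data$pos)
  dplyr::group_by(pairs, .data$snp_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      r <- find_gdmrs(d$t, d$pos, d$p, cutoff = cutoff, maxgap = maxgap,
                      min_sites = min_sites)
      r[, setdiff(names(r), c("chrom", "snp_id"))]
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "snp_id", "n_sites", "mean_t",
                  "mean_p", "sign") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Classify a region cis/trans relative to an interval
#'
#' Cis when the region overlaps the block by at least one bp (1-based
#' inclusive coordinates on both sides); trans otherwise, including other
#' chromosomes.
#'
#' @param regions Tibble with chrom, start, end.
#' @param blocks Tibble with chrom, start1, end1 (e.g. GWAS LD blocks from
#'   [read_bed()]), or snp positions as zero-width blocks.
#' @return The regions with a `cis_flag` column.
#' @export
classify_region <- function(regions, blocks) {
  if (!nrow(blocks)) rlang::abort("no blocks supplied")
  cis <- vapply(seq_len(nrow(regions)), function(i) {
    b <- blocks[blocks$chrom == regions$chrom[i], ]
    any(b$start1 <= regions$end[i] & b$end1 >= regions$start[i])
  }, logical(1))
  dplyr::mutate(regions, cis_flag = ifelse(cis, "cis", "trans"))
}

#' Overlap two region sets
#'
#' Any-bp overlap on 1-based inclusive coordinates, found by a sweep over
#' the sorted sets.
#'
#' @param a,b Region tibbles (chrom, start, end).
#' @return List: `pairs` (tibble of row indices `a_row`, `b_row`), `n_a_hit`
#'   (count of `a` regions with at least one overlap), `n_b_hit`.
#' @export
overlap_regions <- function(a, b) {
  hits <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    bo <- ib[order(b$start[ib])]
    starts <- b$start[bo]
    for (i in ia) {
      # candidates: b regions with start <= a.end; filter on end >= a.start
      last <- findInterval(a$end[i], starts)
      if (last < 1) next
      cand <- bo[seq_len(last)]
      cand <- cand[b$end[cand] >= a$start[i]]
      if (length(cand)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(a_row = i, b_row = cand)
      }
    }
  }
  pairs <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(a_row = integer(0), b_row = integer(0))
  list(pairs = pairs,
       n_a_hit = length(unique(pairs$a_row)),
       n_b_hit = length(unique(pairs$b_row)))
}

#' Cross-dataset replication of a gDMR by member-site p-values
#'
#' @param member_p Replication p-values at the region's member sites
#'   (missing sites dropped; their count is reported).
#' @param alpha Replication threshold on the mean p (default 0.05).
#' @return One-row tibble: mean_p, replicated (NA when no member site is
#'   present), n_used, n_missing.
#' @export
region_replication <- function(member_p, alpha = 0.05) {
  miss <- sum(is.na(member_p))
  pp <- member_p[!is.na(member_p)]
  if (!length(pp)) {
    return(tibble::tibble(mean_p = NA_real_, replicated = NA,
                          n_used = 0L, n_missing = miss))
  }
  mp <- mean(pp)
  tibble::tibble(mean_p = mp, replicated = mp < alpha,
                 n_used = length(pp), n_missing = miss)
}

#' Write gDMRs as a BED file (0-based half-open)
#'
#' name = index SNP, score = mean |t|, strand = effect sign; the output is a
#' valid annotation input for [ld_scores()] / [stratified_regression()].
#'
#' @param regions Region tibble from [find_gdmrs_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gdmr_bed <- function(regions, path) {
  write_bed(tibble::tibble(
    chrom = regions$chrom, start = regions$start - 1L, end = regions$end,
    name = regions$snp_id, score = round(abs(regions$mean_t), 3),
    strand = regions$sign), path)
}
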
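# Putative-site construction, genomic-marker categorization, linear site
# density and cross-cell-line conservation.

#' Putative accessible binding sites
#'
#' Retains motif matches with `motif_pvalue <= pvalue_max` (default 1e-4)
#' whose center lies within a DNase-I hypersensitive interval; all
#' returned sites carry `bound = FALSE`.
#'
#' @param motif_matches [site_set()] of motif-scan matches with
#'   `motif_pvalue`.
#' @param dhs interval data frame (`chrom`, `start`, `end`).
#' @param pvalue_max motif p-value threshold.
#' @return A [site_set()] of putative sites.
#' @export
putative_sites <- function(motif_matches, dhs, pvalue_max = 1e-4) {
  df <- as.data.frame(motif_matches)
  if (nrow(df) > 0 && anyNA(df$motif_pvalue))
    stopf("putative_sites: motif matches without motif_pvalue")
  keep <- if (nrow(df) == 0) logical(0) else
    df$motif_pvalue <= pvalue_max & center_in_intervals(df, dhs)
  df <- df[keep, , drop = FALSE]
  df$bound <- rep(FALSE, nrow(df))
  site_set(df, tf_id(motif_matches), attr(motif_matches, "cell_type"))
}

#' Map ChIP-seq peaks to their best overlapping motif match
#'
#' Each peak that overlaps at least one motif match yields one bound site
#' at the best-scoring (lowest `motif_pvalue`) overlapping match, ties
#' broken by leftmost match start; peaks without an overlapping match are
#' dropped. The peak's SignalValue is carried onto the site.
#'
#' @param peaks [site_set()] of ChIP-seq peaks.
#' @param motif_matches [site_set()] of motif matches for the same TF.
#' @return A [site_set()] of bound sites at motif-match coordinates.
#' @export
map_peaks_to_motifs <- function(peaks, motif_matches) {
  pk <- as.data.frame(peaks)
  mm <- as.data.frame(motif_matches)
  if (nrow(pk) == 0 || nrow(mm) == 0)
    return(site_set(mm[0, , drop = FALSE], tf_id(peaks)))
  hits <- GenomicRanges::findOverlaps(as_granges0(pk), as_granges0(mm))
  if (length(hits) == 0)
    return(site_set(mm[0, , drop = FALSE], tf_id(peaks)))
  h <- data.frame(peak = S4Vectors::queryHits(hits),
                  match = S4Vectors::subjectHits(hits))
  h$p <- mm$motif_pvalue[h$match]
  h$start <- mm$start[h$match]
  h <- h[order(h$peak, h$p, h$start), , drop = FALSE]
  best <- h[!duplicated(h$peak), , drop = FALSE]
  out <- mm[best$match, , drop = FALSE]
  out$signal_value <- pk$signal_value[best$peak]
  out$bound <- TRUE
  out <- out[!duplicated(paste(out$chrom, out$start, out$end, out$strand)),
             , drop = FALSE]
  site_set(out, tf_id(peaks), attr(peaks, "cell_type"))
}

# Upstream-of-TSS windows as 0-based half-open intervals; strand-aware
# when the TSS table carries strand, else the left side is used.
tss_upstream_windows <- function(tss, width) {
  strand <- tss$strand %||% rep(".", nrow(tss))
  minus <- strand == "-"
  data.frame(chrom = tss$chrom,
             start = ifelse(minus, tss$pos, pmax(tss$pos - width, 0)),
             end = ifelse(minus, tss$pos + width, tss$pos),
             stringsAsFactors = FALSE)
}

#' Categorize binding sites by genomic markers
#'
#' Assigns exactly one label per site. Exclusions take precedence:
#' sites in methylated regions are `excluded_methylated`; sites whose
#' center overlaps both H3K27ac and H3K27me3, or both H3K9ac and H3K9me,
#' are `excluded_ambiguous`. A promoter site lies within 2000 bp upstream
#' of a TSS (gene strand when provided) and carries both H3K4me3 and
#' H3K27ac at its center; it is a `strong_promoter` when an H3K36me3 peak
#' overlaps the TSS +/- 1000 bp window by at least 300 bp, else a
#' `weak_promoter`. An enhancer site sits in a chromatin-state enhancer
#' region with H3K4me1: `active_enhancer` with H3K27ac,
#' `inactive_enhancer` without H3K27ac but with H3K27me3. Everything else
#' is `other`. Mark association always uses site-center containment.
#'
#' @param sites a [site_set()] or site data frame.
#' @param marks named list of interval data frames; requires H3K4me1,
#'   H3K4me3, H3K27ac, H3K27me3, H3K9me, H3K9ac, H3K36me3.
#' @param tss data frame with `chrom`, `pos` and optional `strand`.
#' @param chromatin_state enhancer intervals from consensus chromatin
#'   states.
#' @param methylation methylated-region intervals (optional).
#' @param upstream promoter window size upstream of the TSS (bp).
#' @return Character vector of labels, one per site.
#' @export
categorize_sites <- function(sites, marks, tss, chromatin_state,
                             methylation = NULL, upstream = 2000) {
  required <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "H3K9me",
                "H3K9ac", "H3K36me3")
  missing <- setdiff(required, names(marks))
  if (length(missing) > 0)
    stopf("categorize_sites: missing mark track(s): %s",
          paste(missing, collapse = ", "))
  df <- as.data.frame(sites)
  n <- nrow(df)
  if (n == 0) return(character(0))
  in_mark <- lapply(marks[required], function(m) center_in_intervals(df, m))

  up <- tss_upstream_windows(tss, upstream)
  in_upstream <- center_in_intervals(df, up)
  # nearest TSS window (+/- 1000 bp) with an H3K36me3 overlap >= 300 bp
  tssw <- data.frame(chrom = tss$chrom, start = pmax(tss$pos - 1000, 0),
                     end = tss$pos + 1000)
  ov <- GenomicRanges::findOverlaps(as_granges0(tssw),
                                    as_granges0(marks$H3K36me3))
  wid <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(as_granges0(tssw))[S4Vectors::queryHits(ov)],
    IRanges::ranges(as_granges0(marks$H3K36me3))[S4Vectors::subjectHits(ov)]))
  strong_tss <- unique(S4Vectors::queryHits(ov)[wid >= 300])
  in_strong_up <- center_in_intervals(df, up[strong_tss, , drop = FALSE])

  in_state_enh <- center_in_intervals(df, chromatin_state)
  meth <- if (is.null(methylation)) rep(FALSE, n)
          else center_in_intervals(df, methylation)

  amb <- (in_mark$H3K27ac & in_mark$H3K27me3) |
    (in_mark$H3K9ac & in_mark$H3K9me)
  prom <- in_upstream & in_mark$H3K4me3 & in_mark$H3K27ac
  enh <- in_state_enh & in_mark$H3K4me1
  lab <- rep("other", n)
  lab[enh & !in_mark$H3K27ac & in_mark$H3K27me3] <- "inactive_enhancer"
  lab[enh & in_mark$H3K27ac] <- "active_enhancer"
  lab[prom] <- ifelse(in_strong_up[prom], "strong_promoter",
                      "weak_promoter")
  lab[amb] <- "excluded_ambiguous"
  lab[meth] <- "excluded_methylated"
  lab
}

#' Enhancer/promoter classification for structure analyses
#'
#' Evaluates marks within +/- `flank` bp of the site center: enhancer
#' flanks carry H3K4me1 and no H3K4me3; promoter flanks carry a TSS,
#' H3K4me3 and no H3K4me1; anything else is `other`.
#'
#' @param sites a [site_set()] or site data frame.
#' @param marks named list with at least H3K4me1 and H3K4me3 intervals.
#' @param tss data frame with `chrom`, `pos`.
#' @param flank window half-width in bp (default 2000).
#' @return Character vector in `{enhancer, promoter, other}`.
#' @export
categorize_structure_flanks <- function(sites, marks, tss, flank = 2000) {
  stopifnot(flank >= 0)
  df <- as.data.frame(sites)
  n <- nrow(df)
  if (n == 0) return(character(0))
  ctr <- site_center(df$start, df$end)
  win <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(pmax(ctr - flank, 0) + 1,
                                                 ctr + flank))
  has <- function(ivs) IRanges::overlapsAny(win, as_granges0(ivs))
  k4me1 <- has(marks$H3K4me1)
  k4me3 <- has(marks$H3K4me3)
  tss_iv <- data.frame(chrom = tss$chrom, start = tss$pos,
                       end = tss$pos + 1)
  has_tss <- has(tss_iv)
  out <- rep("other", n)
  out[k4me1 & !k4me3] <- "enhancer"
  out[has_tss & k4me3 & !k4me1] <- "promoter"
  out
}

#' Linear binding-site density over 100-kb regions
#'
#' Distributes each site over the fixed region grid with a weight equal to
#' the fraction of a `region_size` window, centered on the site, that
#' overlaps each region; this equals the average of a continuous sliding-
#' window count over the region and conserves total site mass for sites
#' whose window lies fully inside the chromosome.
#'
#' @param sites a [site_set()] or site data frame.
#' @param structure a [genome_structure()] supplying the region grid, or
#'   `NULL` to derive the grid from the sites (regions
#'   `0, region_size, ...` per chromosome).
#' @param region_size region size in bp (default 100 kb; taken from the
#'   structure when given).
#' @return A `linear_density_track` data frame with `chrom`, `start`,
#'   `value` (weighted site count per region).
#' @export
linear_density <- function(sites, structure = NULL, region_size = 1e5) {
  df <- as.data.frame(sites)
  if (!is.null(structure)) region_size <- structure$particle_size
  grid <- if (!is.null(structure)) {
    structure$particles[, c("chrom", "start")]
  } else {
    do.call(rbind, lapply(unique(df$chrom), function(cc) {
      mx <- max(df$end[df$chrom == cc]) + region_size
      data.frame(chrom = cc,
                 start = seq(0, mx, by = region_size))
    }))
  }
  value <- numeric(nrow(grid))
  half <- region_size / 2
  ctr <- site_center(df$start, df$end)
  for (i in seq_len(nrow(df))) {
    sel <- which(grid$chrom == df$chrom[i])
    if (length(sel) == 0) next
    w_lo <- ctr[i] - half
    w_hi <- ctr[i] + half
    touch <- sel[grid$start[sel] < w_hi &
                   grid$start[sel] + region_size > w_lo]
    for (g in touch) {
      ov <- min(w_hi, grid$start[g] + region_size) -
        max(w_lo, grid$start[g])
      value[g] <- value[g] + ov / region_size
    }
  }
  out <- data.frame(chrom = grid$chrom, start = grid$start, value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("linear_density_track", "data.frame")
  out
}

#' Binding-site conservation between two cell lines
#'
#' A peak of set A is conserved when some peak of set B overlaps its
#' center with a center-to-center distance strictly below
#' `max_center_dist`; when several B peaks qualify the nearest center
#' wins. Returns the conserved fraction and the per-peak match.
#'
#' @param peaks_a,peaks_b [site_set()]s on the same assembly.
#' @param max_center_dist center-to-center limit in bp (default 300).
#' @return List with `fraction` and a per-A-peak data frame `matches`
#'   (`conserved`, `match` index into B, `center_dist`).
#' @export
conservation_map <- function(peaks_a, peaks_b, max_center_dist = 300) {
  a <- as.data.frame(peaks_a)
  b <- as.data.frame(peaks_b)
  n <- nrow(a)
  res <- data.frame(conserved = rep(FALSE, n), match = NA_integer_,
                    center_dist = NA_real_)
  if (n == 0)
    return(list(fraction = NA_real_, matches = res))
  if (nrow(b) > 0) {
    hits <- GenomicRanges::findOverlaps(centers_granges(a), as_granges0(b))
    if (length(hits) > 0) {
      qa <- S4Vectors::queryHits(hits)
      sb <- S4Vectors::subjectHits(hits)
      dist <- abs(site_center(a$start, a$end)[qa] -
                    site_center(b$start, b$end)[sb])
      ok <- dist < max_center_dist
      h <- data.frame(a = qa[ok], b = sb[ok], d = dist[ok])
      h <- h[order(h$a, h$d), , drop = FALSE]
      h <- h[!duplicated(h$a), , drop = FALSE]
      res$conserved[h$a] <- TRUE
      res$match[h$a] <- h$b
      res$center_dist[h$a] <- h$d
    }
  }
  list(fraction = mean(res$conserved), matches = res)
}
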
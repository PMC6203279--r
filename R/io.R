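#' Read binding sites from BED-style files
#'
#' Parses BED6, ENCODE narrowPeak (10 columns) or broadPeak (9 columns)
#' files into a [site_set()]. Coordinates are kept 0-based half-open;
#' narrowPeak/broadPeak column 7 becomes `signal_value` and the summit
#' offset (narrowPeak column 10) is ignored.
#'
#' @param path file path.
#' @param format one of `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @param tf_id TF identifier for the resulting set (default: file stem).
#' @param bound whether the sites are ChIP-seq identified (`TRUE`) or
#'   putative (`FALSE`).
#' @param chroms optional character vector of known chromosomes; rows on
#'   other chromosomes are skipped with a warning when
#'   `unknown_chrom = "skip"` or raise an error when `"error"`.
#' @param unknown_chrom see `chroms`.
#' @return A [site_set()].
#' @export
read_sites <- function(path, format = c("narrowPeak", "bed6", "broadPeak"),
                       tf_id = NULL, bound = NA, chroms = NULL,
                       unknown_chrom = c("skip", "error")) {
  format <- match.arg(format)
  unknown_chrom <- match.arg(unknown_chrom)
  tf_id <- tf_id %||% sub("\\.[^.]*$", "", basename(path))
  ncol_needed <- switch(format, bed6 = 6L, broadPeak = 9L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(site_set(data.frame(chrom = character(), start = integer(),
                               end = integer()), tf_id))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad) > 0)
    stopf("%s line %d: expected >= %d fields for %s, found %d",
          path, bad[1], ncol_needed, format, nf[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stopf("%s line %d: non-numeric start/end",
          path, which(is.na(start) | is.na(end))[1])
  if (any(end <= start))
    stopf("%s line %d: end <= start", path, which(end <= start)[1])
  df <- data.frame(
    chrom = m[, 1], start = start, end = end, name = m[, 4],
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "."),
    stringsAsFactors = FALSE
  )
  df$signal_value <- if (ncol_needed >= 7)
    suppressWarnings(as.numeric(m[, 7])) else 0
  df$signal_value[is.na(df$signal_value) | df$signal_value < 0] <- 0
  if (!is.na(bound)) df$bound <- bound
  if (!is.null(chroms)) {
    unk <- !(df$chrom %in% chroms)
    if (any(unk)) {
      if (unknown_chrom == "error")
        stopf("%s: unknown chromosome '%s'", path, df$chrom[which(unk)[1]])
      warnf("%s: skipping %d site(s) on unknown chromosomes", path, sum(unk))
      df <- df[!unk, , drop = FALSE]
    }
  }
  site_set(df, tf_id)
}

#' Write a site set as BED6 or narrowPeak
#'
#' @param x a [site_set()].
#' @param path output file.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(x, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  cols <- data.frame(x$chrom, x$start, x$end, x$name, 0L, x$strand)
  if (format == "narrowPeak") {
    cols <- cbind(cols, x$signal_value,
                  ifelse(is.na(x$motif_pvalue), -1, -log10(x$motif_pvalue)),
                  -1, -1)
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read interval annotations (BED3/BED4)
#'
#' Generic reader for DHS regions, histone-mark peaks, chromatin states and
#' compartment annotations: a tab-separated file with `chrom start end`
#' and an optional fourth label column (e.g. sub-compartment `A1`, `B2`).
#'
#' @param path file path.
#' @return Data frame with `chrom`, `start`, `end` and, if present, `label`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3))
    stopf("%s line %d: expected >= 3 fields",
          path, which(lengths(fields) < 3)[1])
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.integer(vapply(fields, `[`, "", 2)),
    end = as.integer(vapply(fields, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start))
    stopf("%s line %d: end <= start", path, which(df$end <= df$start)[1])
  if (all(lengths(fields) >= 4)) df$label <- vapply(fields, `[`, "", 4)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read a per-chromosome Hi-C contact map from sparse TSV triples
#'
#' The expected dialect is one chromosome per file, tab-separated columns
#' `chrom, bin_i_start, bin_j_start, normalized[, raw]`; bin starts must be
#' multiples of `bin_size`. When the raw column is absent, raw counts
#' default to the rounded normalized counts. Duplicate `(i, j)`/`(j, i)`
#' entries with conflicting values violate symmetric storage and raise an
#' error.
#'
#' @param path file path.
#' @param bin_size bin size in bp (default 5000).
#' @param n_bins number of bins; default inferred from the largest bin start.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, bin_size = 5000, n_bins = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("%s: expected >= 4 columns", path)
  chrom <- unique(df[[1]])
  if (length(chrom) != 1) stopf("%s: one chromosome per map, found %d",
                                path, length(chrom))
  if (any(df[[2]] %% bin_size != 0 | df[[3]] %% bin_size != 0))
    stopf("%s: bin starts are not multiples of bin_size %d", path, bin_size)
  bi <- df[[2]] %/% bin_size
  bj <- df[[3]] %/% bin_size
  norm <- as.numeric(df[[4]])
  raw <- if (ncol(df) >= 5) as.numeric(df[[5]]) else round(norm)
  # canonical upper-triangle orientation
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    grp <- split(seq_along(key)[d], key[d])
    for (g in grp) {
      if (length(unique(norm[g])) > 1 || length(unique(raw[g])) > 1)
        stopf("%s: conflicting duplicate entries for bin pair (%d, %d)",
              path, lo[g[1]] * bin_size, hi[g[1]] * bin_size)
    }
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; norm <- norm[keep]; raw <- raw[keep]
  }
  contact_map(chrom = chrom, bin_size = bin_size, bin_i = lo, bin_j = hi,
              normalized = norm, raw = raw, n_bins = n_bins)
}

#' Write a contact map as sparse TSV triples
#'
#' @param map a [contact_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  up <- which(upper.tri(map$norm, diag = TRUE) &
                (map$norm != 0 | map$raw != 0), arr.ind = TRUE)
  df <- data.frame(map$chrom, (up[, 1] - 1L) * map$bin_size,
                   (up[, 2] - 1L) * map$bin_size,
                   map$norm[up], map$raw[up])
  df <- df[order(df[[2]], df[[3]]), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-model genome structure
#'
#' Whitespace-separated table with columns
#' `model_index, chrom, particle_start, x, y, z`. All models must cover an
#' identical, sequentially ordered particle list. The particle radius is
#' estimated as half the median 3D distance between sequentially adjacent
#' intra-chromosome particles (pooled over models): model units are
#' arbitrary, and in the source structures the repulsive radius corresponds
#' to half the ideal sequential particle separation.
#'
#' @param path file path.
#' @param particle_size particle size in bp (default 100 kb).
#' @param compartment optional per-particle `A`/`B` labels, or an interval
#'   annotation data frame (see [read_intervals()]) from which labels are
#'   looked up by particle midpoint.
#' @return A [genome_structure()].
#' @export
read_structure <- function(path, particle_size = 1e5, compartment = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopf("%s: expected 6 columns", path)
  names(df) <- c("model", "chrom", "start", "x", "y", "z")
  models <- sort(unique(df$model))
  parts <- lapply(models, function(m) {
    sub <- df[df$model == m, ]
    paste(sub$chrom, sub$start)
  })
  if (length(unique(vapply(parts, paste, "", collapse = ";"))) != 1)
    stopf("%s: models have differing particle lists", path)
  first <- df[df$model == models[1], ]
  for (cc in unique(first$chrom)) {
    s <- first$start[first$chrom == cc]
    if (is.unsorted(s, strictly = TRUE))
      stopf("%s: particle starts not strictly increasing within %s",
            path, cc)
  }
  n <- nrow(first)
  coords <- array(NA_real_, dim = c(n, 3, length(models)))
  for (k in seq_along(models)) {
    sub <- df[df$model == models[k], ]
    coords[, , k] <- as.matrix(sub[, c("x", "y", "z")])
  }
  genome_structure(
    particles = data.frame(chrom = first$chrom, start = first$start,
                           stringsAsFactors = FALSE),
    coords = coords, particle_size = particle_size,
    compartment = compartment
  )
}

#' Write a genome structure in the 6-column text dialect
#'
#' @param structure a [genome_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  m <- dim(structure$coords)[3]
  rows <- do.call(rbind, lapply(seq_len(m), function(k) {
    data.frame(model = k, chrom = structure$particles$chrom,
               start = structure$particles$start,
               x = structure$coords[, 1, k],
               y = structure$coords[, 2, k],
               z = structure$coords[, 3, k])
  }))
  utils::write.table(format(rows, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
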
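#' Specification for synthetic study data
#'
#' Describes the synthetic inputs the generator produces: per-chromosome
#' Hi-C maps with power-law distance decay (contact ~ separation^-alpha)
#' and multiplicative log-normal noise, TF site sets with controllable
#' linear density, occupancy and compartment bias, planted pairwise contact
#' enrichment between designated TF site sets, and particle-on-string
#' genome structures with alternating A/B blocks and planted spatial
#' clusters. All draws come from one seeded generator, so identical specs
#' give bit-identical outputs.
#'
#' @param seed integer RNG seed (recorded in outputs).
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param bin_size Hi-C bin size in bp.
#' @param decay_exponent alpha in contact ~ separation^-alpha.
#' @param base_contact normalized contact at one-bin separation.
#' @param noise_sd sdlog of the multiplicative log-normal noise (0 = none).
#' @param tf_specs data frame with `tf_id`, `n_sites` (per chromosome),
#'   `occupancy_target` in \[0,1\], `compartment_bias` in \[0,1\] (0 =
#'   uniform, 1 = all sites in A blocks).
#' @param planted_pairs data frame with `tf_a`, `tf_b`, `enrichment`
#'   (>= 1): bin pairs holding an A site and a B site get their baseline
#'   contact multiplied by `enrichment`.
#' @param compartment_block length in bp of alternating A/B blocks.
#' @param site_width width of generated sites in bp.
#' @param n_particles structure particles per chromosome (default
#'   `chrom_length / particle_size`).
#' @param particle_size structure particle size in bp (100 kb).
#' @param n_models number of structure models.
#' @param jitter per-model coordinate jitter, in particle radii (< 0.5 so
#'   the model-consistency filters pass by construction).
#' @param cluster_radius radius, in particle radii, of a planted spatial
#'   cluster sphere.
#' @param cluster_frac fraction of a planted TF's sites placed inside its
#'   cluster sphere.
#' @param planted_clusters list of character vectors of `tf_id`s; the TFs
#'   in one vector share one cluster sphere.
#' @param n_dhs background DHS intervals per chromosome.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chroms = 1L,
                           chrom_length = 6e6,
                           bin_size = 5000,
                           decay_exponent = 1,
                           base_contact = 300,
                           noise_sd = 0.3,
                           tf_specs = data.frame(
                             tf_id = c("TF1", "TF2"),
                             n_sites = 60L,
                             occupancy_target = 1,
                             compartment_bias = 0),
                           planted_pairs = NULL,
                           compartment_block = 5e5,
                           site_width = 200,
                           n_particles = NULL,
                           particle_size = 1e5,
                           n_models = 10L,
                           jitter = 0.2,
                           cluster_radius = 1.2,
                           cluster_frac = 0.5,
                           planted_clusters = list(),
                           n_dhs = 150L) {
  spec <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_length = chrom_length, bin_size = bin_size,
               decay_exponent = decay_exponent, base_contact = base_contact,
               noise_sd = noise_sd, tf_specs = tf_specs,
               planted_pairs = planted_pairs,
               compartment_block = compartment_block,
               site_width = site_width,
               n_particles = as.integer(n_particles %||%
                                          (chrom_length %/% particle_size)),
               particle_size = particle_size, n_models = as.integer(n_models),
               jitter = jitter, cluster_radius = cluster_radius,
               cluster_frac = cluster_frac,
               planted_clusters = planted_clusters, n_dhs = as.integer(n_dhs))
  stopifnot(is.data.frame(tf_specs),
            all(c("tf_id", "n_sites") %in% names(tf_specs)))
  if (is.null(tf_specs$occupancy_target)) spec$tf_specs$occupancy_target <- 1
  if (is.null(tf_specs$compartment_bias)) spec$tf_specs$compartment_bias <- 0
  if (any(spec$tf_specs$occupancy_target < 0 |
            spec$tf_specs$occupancy_target > 1))
    stopf("synthetic_spec: occupancy_target outside [0, 1]")
  if (any(spec$tf_specs$compartment_bias < 0 |
            spec$tf_specs$compartment_bias > 1))
    stopf("synthetic_spec: compartment_bias outside [0, 1]")
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("tf_a", "tf_b", "enrichment") %in% names(planted_pairs)))
    if (any(planted_pairs$enrichment < 1))
      stopf("synthetic_spec: planted enrichment factors must be >= 1")
    known <- spec$tf_specs$tf_id
    if (!all(c(planted_pairs$tf_a, planted_pairs$tf_b) %in% known))
      stopf("synthetic_spec: planted pair names an unknown TF")
  }
  structure(spec, class = "synthetic_spec")
}

syn_chroms <- function(spec) paste0("chr", seq_len(spec$n_chroms))

# A/B label of positions under the alternating block layout.
block_compartment <- function(pos, block) {
  ifelse((pos %/% block) %% 2 == 0, "A", "B")
}

#' Compartment annotation of the synthetic genome
#'
#' @param spec a [synthetic_spec()].
#' @return Interval data frame with `chrom`, `start`, `end`, `label`
#'   matching the generator's alternating A/B block layout.
#' @export
synthetic_compartments <- function(spec) {
  out <- lapply(syn_chroms(spec), function(cc) {
    starts <- seq(0, spec$chrom_length - 1, by = spec$compartment_block)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + spec$compartment_block,
                          spec$chrom_length),
               label = block_compartment(starts, spec$compartment_block),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sample site bins for every TF on one chromosome (compartment-biased).
sample_site_bins <- function(spec, n_bins) {
  comp <- block_compartment((seq_len(n_bins) - 1) * spec$bin_size,
                            spec$compartment_block)
  lapply(seq_len(nrow(spec$tf_specs)), function(k) {
    bias <- spec$tf_specs$compartment_bias[k]
    w <- ifelse(comp == "A", 0.5 + bias / 2, 0.5 - bias / 2)
    if (all(w == 0)) w[] <- 1
    sort(sample.int(n_bins, spec$tf_specs$n_sites[k], prob = w)) - 1L
  })
}

sites_from_bins <- function(spec, chrom, bins) {
  width <- spec$site_width
  start <- bins * spec$bin_size + (spec$bin_size - width) %/% 2
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

#' Generate synthetic Hi-C contact maps with planted co-localization
#'
#' Produces one [contact_map()] per chromosome plus the TF site sets used
#' to plant signal. The baseline normalized count at bin separation `s` is
#' `base_contact * s^-decay_exponent`, multiplied by log-normal noise with
#' `sdlog = noise_sd`; for every planted pair the bin pairs holding a site
#' of each member are further multiplied by the enrichment factor. Raw
#' counts are Poisson draws around the normalized counts. With
#' `noise_sd = 0` and no planted pairs the map equals the power-law
#' closed form exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `maps` (named by chromosome), `sites` (named list of
#'   [site_set()]s) and `spec`.
#' @export
make_contact_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_bins <- as.integer(spec$chrom_length %/% spec$bin_size)
    if (any(spec$tf_specs$n_sites > n_bins))
      stopf("make_contact_map: n_sites exceeds the %d available bins",
            n_bins)
    tfs <- spec$tf_specs$tf_id
    site_dfs <- stats::setNames(
      replicate(length(tfs), list(), simplify = FALSE), tfs)
    maps <- list()
    for (cc in syn_chroms(spec)) {
      bins <- sample_site_bins(spec, n_bins)
      names(bins) <- tfs
      for (tf in tfs) {
        df <- sites_from_bins(spec, cc, bins[[tf]])
        occ <- spec$tf_specs$occupancy_target[match(tf, tfs)]
        df$bound <- stats::runif(nrow(df)) < occ
        site_dfs[[tf]] <- c(site_dfs[[tf]], list(df))
      }
      up <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
      s <- up[, 2] - up[, 1]
      mu <- spec$base_contact * s^(-spec$decay_exponent)
      if (spec$noise_sd > 0)
        mu <- mu * exp(stats::rnorm(length(mu), 0, spec$noise_sd))
      norm <- matrix(0, n_bins, n_bins)
      norm[up] <- mu
      if (!is.null(spec$planted_pairs)) {
        for (r in seq_len(nrow(spec$planted_pairs))) {
          a <- bins[[spec$planted_pairs$tf_a[r]]] + 1L
          b <- bins[[spec$planted_pairs$tf_b[r]]] + 1L
          f <- spec$planted_pairs$enrichment[r]
          fm <- matrix(1, n_bins, n_bins)
          fm[a, b] <- f
          fm[b, a] <- f
          norm[up] <- norm[up] * fm[up]
        }
      }
      norm <- norm + t(norm)
      diag(norm) <- spec$base_contact
      rawm <- matrix(0, n_bins, n_bins)
      rawm[up] <- stats::rpois(length(mu), norm[up])
      rawm <- rawm + t(rawm)
      diag(rawm) <- stats::rpois(n_bins, spec$base_contact)
      maps[[cc]] <- structure(
        list(chrom = cc, bin_size = spec$bin_size, n_bins = n_bins,
             norm = norm, raw = rawm, bin_raw_total = rowSums(rawm),
             mask = rep(TRUE, n_bins)),
        class = "contact_map")
    }
    sites <- lapply(tfs, function(tf)
      site_set(do.call(rbind, site_dfs[[tf]]), tf, "synthetic"))
    names(sites) <- tfs
    list(maps = maps, sites = sites, spec = spec)
  })
}

#' Generate a synthetic multi-model genome structure
#'
#' Each chromosome is an off-lattice 3D random walk of 100-kb particles
#' with step length twice the particle radius; A/B compartments alternate
#' in sequential blocks. TFs listed in `planted_clusters` have
#' `cluster_frac` of their sites assigned to particles inside a shared
#' sphere of `cluster_radius` particle radii (error when the sphere
#' captures no particles); remaining sites fall on random particles. The
#' model ensemble applies an independent random rigid rotation,
#' translation and small coordinate jitter to every model, so the
#' model-consistency filters pass by construction at `jitter < 0.5`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `structure` (a [genome_structure()]), `sites` (named
#'   list of [site_set()]s) and `spec`.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    r <- 0.5  # particle radius in model units; step length 2r
    n_p <- spec$n_particles
    parts <- list(); base <- list()
    for (cc in syn_chroms(spec)) {
      steps <- matrix(stats::rnorm(3 * n_p), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * 2 * r
      xyz <- apply(steps, 2, cumsum)
      xyz <- sweep(xyz, 2, stats::rnorm(3, sd = 2 * r), "+")
      base[[cc]] <- xyz
      starts <- (seq_len(n_p) - 1L) * spec$particle_size
      parts[[cc]] <- data.frame(chrom = cc, start = starts,
                                stringsAsFactors = FALSE)
    }
    particles <- do.call(rbind, parts)
    coords0 <- do.call(rbind, base)
    n <- nrow(coords0)

    # assign sites to particles
    tfs <- spec$tf_specs$tf_id
    cluster_of <- stats::setNames(rep(NA_integer_, length(tfs)), tfs)
    for (k in seq_along(spec$planted_clusters))
      cluster_of[spec$planted_clusters[[k]]] <- k
    # Planted spatial clusters are hubs of *sequentially distant* loci:
    # member particles are picked spread out along the chromosomes (so
    # the >3-particle sequential exclusion never removes their pairs) and
    # their coordinates are relocated into a tight designated sphere.
    # Sphere centers are kept well apart so distinct clusters stay
    # distinct. The sphere radius should not exceed half the proximity
    # threshold in radii, or in-sphere pairs stop being mutually close.
    n_clusters <- length(spec$planted_clusters)
    sphere_r <- spec$cluster_radius * r
    n_members <- max(2L, round(0.08 * n))
    if (n_clusters > 0 && (n_members + 1) * 5 * n_clusters > n)
      stopf("make_structure: too few particles for %d planted clusters",
            n_clusters)
    # centers sit inside the occupied region (walks start near the
    # origin) but 10 radii apart from one another
    centers <- lapply(seq_len(n_clusters), function(k) {
      c(10 * r * (k - (n_clusters + 1) / 2), 0, 0) + stats::rnorm(3, sd = r)
    })
    taken <- integer(0)
    chrom_idx <- unlist(lapply(unique(particles$chrom), function(cc)
      seq_len(sum(particles$chrom == cc))))
    members <- lapply(seq_len(n_clusters), function(k) {
      mem <- integer(0)
      for (i in sample.int(n)) {
        near_seq <- abs(chrom_idx - chrom_idx[i]) <= 4 &
          particles$chrom == particles$chrom[i]
        if (any(c(mem, taken) %in% which(near_seq))) next
        mem <- c(mem, i)
        if (length(mem) == n_members) break
      }
      if (length(mem) < 2)
        stopf("make_structure: cluster sphere too small for requested sites")
      taken <<- c(taken, mem)
      u <- matrix(stats::rnorm(3 * length(mem)), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) *
        (stats::runif(length(mem))^(1 / 3) * sphere_r)
      coords0[mem, ] <<- sweep(u, 2, centers[[k]], "+")
      mem
    })
    site_sets <- list()
    for (tf in tfs) {
      n_sites <- spec$tf_specs$n_sites[match(tf, tfs)] * spec$n_chroms
      ci <- cluster_of[[tf]]
      if (!is.na(ci)) {
        n_in <- round(spec$cluster_frac * n_sites)
        if (length(members[[ci]]) == 0 && n_in > 0)
          stopf("make_structure: cluster sphere for '%s' contains no particles",
                tf)
        pidx <- c(sample(members[[ci]], n_in, replace = TRUE),
                  sample.int(n, n_sites - n_in, replace = TRUE))
      } else {
        pidx <- sample.int(n, n_sites, replace = TRUE)
      }
      pidx <- sort(pidx)
      # unique in-particle offsets so site keys never collide
      rank_in <- stats::ave(pidx, pidx, FUN = seq_along)
      start <- particles$start[pidx] + 1000L + (rank_in - 1L) * 500L
      site_sets[[tf]] <- site_set(
        data.frame(chrom = particles$chrom[pidx], start = start,
                   end = start + spec$site_width, bound = TRUE),
        tf, "synthetic")
    }

    coords <- array(NA_real_, dim = c(n, 3, spec$n_models))
    for (m in seq_len(spec$n_models)) {
      rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(rot) < 0) rot[, 1] <- -rot[, 1]
      jit <- matrix(stats::rnorm(3 * n, sd = spec$jitter * r), ncol = 3)
      coords[, , m] <- (coords0 + jit) %*% rot +
        matrix(stats::rnorm(3, sd = r), n, 3, byrow = TRUE)
    }
    comp <- block_compartment(particles$start + spec$particle_size / 2,
                              spec$compartment_block)
    structure_obj <- genome_structure(particles, coords,
                                      particle_size = spec$particle_size,
                                      compartment = comp)
    list(structure = structure_obj, sites = site_sets, spec = spec)
  })
}

#' Generate putative/bound site sets with annotation tracks
#'
#' Lays out promoter and enhancer cassettes along each chromosome (TSSs
#' with H3K4me3/H3K27ac and, for strong promoters, H3K36me3; chromatin-
#' state enhancers with H3K4me1 and H3K27ac or H3K27me3), DHS intervals at
#' the cassettes plus random background DHS, occasional ambiguous
#' (H3K27ac+H3K27me3) and methylated regions, and then places putative
#' motif sites inside DHS intervals. Each putative site is bound with
#' probability `occupancy_target`, optionally multiplied by a per-site
#' propensity to plant an occupancy gradient.
#'
#' @param spec a [synthetic_spec()].
#' @param propensity optional function `(n) -> multiplier in [0, 1]^n` or
#'   numeric vector recycled per TF, modulating the bound probability.
#' @return List with `putative` and `bound` (named lists of
#'   [site_set()]s), `dhs`, `tss`, `marks` (named list of interval data
#'   frames), `chromatin_state`, `methylation` and `spec`.
#' @export
make_occupancy_sites <- function(spec, propensity = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 2L, {
    L <- spec$chrom_length
    iv <- function(chrom, s, e) data.frame(chrom = chrom, start = s, end = e,
                                           stringsAsFactors = FALSE)
    empty_iv <- iv(character(0), integer(0), integer(0))
    marks <- stats::setNames(rep(list(empty_iv), 7),
                             c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3",
                               "H3K9me", "H3K9ac", "H3K36me3"))
    dhs <- NULL; tss <- NULL; state <- NULL; meth <- NULL
    for (cc in syn_chroms(spec)) {
      tpos <- seq(25000, L - 50000, by = 50000)
      strong <- seq_along(tpos) %% 2 == 1
      tss <- rbind(tss, data.frame(chrom = cc, pos = tpos, strand = "+",
                                   stringsAsFactors = FALSE))
      marks$H3K4me3 <- rbind(marks$H3K4me3, iv(cc, tpos - 1500, tpos + 500))
      marks$H3K27ac <- rbind(marks$H3K27ac, iv(cc, tpos - 1500, tpos + 500))
      marks$H3K36me3 <- rbind(marks$H3K36me3,
                              iv(cc, tpos[strong] - 200, tpos[strong] + 800))
      epos <- tpos + 25000
      active <- seq_along(epos) %% 2 == 1
      state <- rbind(state, iv(cc, epos - 1000, epos + 1000))
      marks$H3K4me1 <- rbind(marks$H3K4me1, iv(cc, epos - 800, epos + 800))
      marks$H3K27ac <- rbind(marks$H3K27ac,
                             iv(cc, epos[active] - 500, epos[active] + 500))
      marks$H3K27me3 <- rbind(marks$H3K27me3,
                              iv(cc, epos[!active] - 500, epos[!active] + 500))
      # cassette DHS: promoters sit just upstream of the TSS
      dhs <- rbind(dhs, iv(cc, tpos - 900, tpos - 300),
                   iv(cc, epos - 300, epos + 300))
      # H3K9 marks: acetylation at active cassettes, methylation decoys
      # in between (never overlapping H3K9ac)
      marks$H3K9ac <- rbind(marks$H3K9ac,
                            iv(cc, epos[active] - 500, epos[active] + 500))
      marks$H3K9me <- rbind(marks$H3K9me,
                            iv(cc, tpos + 36000, tpos + 37000))
      # ambiguous and methylated decoy regions, away from cassettes
      amb <- tpos[c(TRUE, FALSE, FALSE)] + 12000
      marks$H3K27ac <- rbind(marks$H3K27ac, iv(cc, amb - 400, amb + 400))
      marks$H3K27me3 <- rbind(marks$H3K27me3, iv(cc, amb - 400, amb + 400))
      meth <- rbind(meth, iv(cc, tpos[c(FALSE, TRUE, FALSE)] + 12000 - 400,
                             tpos[c(FALSE, TRUE, FALSE)] + 12000 + 400))
      if (spec$n_dhs > 0) {
        bg <- sort(sample(seq(5000, L - 5000, by = 1000), spec$n_dhs))
        dhs <- rbind(dhs, iv(cc, bg - 200, bg + 200))
      }
    }
    marks <- lapply(marks, function(m)
      if (nrow(m) > 0) m[order(m$chrom, m$start), ] else m)
    dhs <- dhs[order(dhs$chrom, dhs$start), ]

    tfs <- spec$tf_specs$tf_id
    putative <- list(); bound <- list()
    for (k in seq_along(tfs)) {
      n_sites <- spec$tf_specs$n_sites[k] * spec$n_chroms
      pick <- sample.int(nrow(dhs), n_sites, replace = TRUE)
      ctr <- site_center(dhs$start[pick], dhs$end[pick])
      # stagger duplicates within one DHS to keep site keys unique
      ord <- order(pick)
      shift <- integer(n_sites)
      shift[ord] <- (stats::ave(pick[ord], pick[ord], FUN = seq_along) - 1L) * 14L
      start <- ctr - 6L + shift
      # overlapping DHS intervals can still collide; nudge repeats apart
      repeat {
        key <- paste(dhs$chrom[pick], start)
        if (!anyDuplicated(key)) break
        start <- start + (stats::ave(seq_along(key), key,
                                     FUN = seq_along) - 1L)
      }
      df <- data.frame(chrom = dhs$chrom[pick], start = start,
                       end = start + 12L,
                       motif_pvalue = 10^-stats::runif(n_sites, 4, 8),
                       signal_value = stats::rexp(n_sites, 1 / 5),
                       stringsAsFactors = FALSE)
      p_bound <- rep(spec$tf_specs$occupancy_target[k], n_sites)
      if (!is.null(propensity)) {
        mult <- if (is.function(propensity)) propensity(n_sites)
                else rep_len(propensity, n_sites)
        p_bound <- pmin(pmax(p_bound * mult, 0), 1)
      }
      df$bound <- stats::runif(n_sites) < p_bound
      putative[[tfs[k]]] <- site_set(df, tfs[k], "synthetic")
      bdf <- df[df$bound, , drop = FALSE]
      bound[[tfs[k]]] <- site_set(bdf, tfs[k], "synthetic")
    }
    list(putative = putative, bound = bound, dhs = dhs, tss = tss,
         marks = marks, chromatin_state = state, methylation = meth,
         spec = spec)
  })
}
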
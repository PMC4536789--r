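# Synthetic-data generators: 3C-style decay profiles with replicate
# noise, tiled genomes of TADs carrying epigenetic-class labels, and
# sampled binned contact maps. Every generator is seed-deterministic and
# records its ground truth, so the whole pipeline can be exercised with
# known answers and no external data.

.local_seed <- function(seed) {
  # Scoped RNG: run with `seed`, then restore the caller's RNG state.
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  set.seed(seed)
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }
  # caller registers restore via on.exit
  restore
}

#' Replicate-noise specification for simulated 3C assays
#'
#' Emulates the replicate structure of quantitative 3C: `n_assays`
#' independent assays, each quantified in `n_tech` technical replicates
#' (defaults 3 x 3), with multiplicative log-normal measurement noise of
#' log-scale standard deviation `sigma_log` (3C-qPCR error is
#' scale-proportional). The reported frequency is the mean of the assay
#' means and the SEM is the standard error across assay means.
#'
#' @param sigma_log Standard deviation of the log-normal noise, `>= 0`.
#' @param n_assays Number of independent assays, `>= 1`.
#' @param n_tech Technical replicates per assay, `>= 1`.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_log = 0, n_assays = 3, n_tech = 3) {
  stopifnot(is.numeric(sigma_log), sigma_log >= 0,
            n_assays >= 1, n_tech >= 1)
  structure(list(sigma_log = sigma_log, n_assays = as.integer(n_assays),
                 n_tech = as.integer(n_tech)),
            class = "noise_spec")
}

#' Simulate a quantitative-3C contact profile
#'
#' Draws a [contact_profile()] from the unconstrained (no `D`, `P`) or
#' statistical-helix contact-frequency model with the replicate structure
#' of [noise_spec()]: each observation is the mean over `n_assays` assay
#' means of `n_tech` technical draws `X(s) * exp(eps)`,
#' `eps ~ N(0, sigma_log^2)`; the SEM is computed across assay means.
#' With `sigma_log = 0` the frequencies equal the exact model curve and
#' all SEMs are 0.
#'
#' @param separations_kb Genomic separations in kb, strictly positive.
#' @param K,L,S Local chromatin truth parameters (see
#'   [contact_frequency()]).
#' @param D,P Optional statistical-helix truth parameters (nm).
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param anchor_id,locus,cell_type,tad_class,fixed_L Profile metadata
#'   (see [contact_profile()]); `fixed_L` defaults to the truth `L`.
#' @return A `contact_profile` whose `truth` attribute records all
#'   generator parameters.
#' @examples
#' simulate_3c_profile(seq(5, 100, 5), K = 1.07e3, L = 9.7, S = 2.7,
#'                     D = 255, P = 201,
#'                     noise = noise_spec(0.1), seed = 1)
#' @export
simulate_3c_profile <- function(separations_kb, K, L, S, D = NULL, P = NULL,
                                noise = noise_spec(), seed = NULL,
                                anchor_id = "sim", locus = "sim",
                                cell_type = "synthetic",
                                tad_class = "unknown", fixed_L = L) {
  stopifnot(inherits(noise, "noise_spec"))
  restore <- .local_seed(seed)
  if (!is.null(restore)) on.exit(restore(), add = TRUE)
  mu <- model_curve(separations_kb, K = K, L = L, S = S, D = D, P = P)
  n_s <- length(separations_kb)
  freq <- sem <- numeric(n_s)
  for (i in seq_len(n_s)) {
    draws <- matrix(
      mu[i] * exp(stats::rnorm(noise$n_tech * noise$n_assays,
                               sd = noise$sigma_log)),
      nrow = noise$n_tech
    )
    assay_means <- colMeans(draws)
    freq[i] <- mean(assay_means)
    sem[i] <- if (noise$n_assays > 1) {
      stats::sd(assay_means) / sqrt(noise$n_assays)
    } else 0
  }
  out <- contact_profile(
    separations_kb, freq, sem = sem, anchor_id = anchor_id, locus = locus,
    cell_type = cell_type, tad_class = tad_class, fixed_L = fixed_L
  )
  attr(out, "truth") <- list(K = K, L = L, S = S, D = D, P = P,
                             noise = noise, seed = seed)
  out
}

# Local chromatin truth per epigenetic class; defaults are the fly
# chromosome-2L medians (cross-linking scale K, compaction L in nm/kb,
# Kuhn segment S in kb) for the four chromatin colours: D1 "red" active,
# D2 "black" unmarked, D3 "blue" Polycomb, D4 "green" HP1.
.DEFAULT_CLASS_PARAMS <- list(
  D1 = c(K = 0.852e-9, L = 10.81, S = 4.150),
  D2 = c(K = 1.487e-9, L = 10.56, S = 4.918),
  D3 = c(K = 1.340e-9, L = 10.61, S = 4.849),
  D4 = c(K = 2.405e-9, L = 10.32, S = 5.296)
)

# Class mixing proportions default to the observed share of fitted
# virtual-3C profiles per colour on fly chromosome 2L
# (990/2481/624/239 fits for D1/D2/D3/D4).
.DEFAULT_CLASS_PROPORTIONS <- c(D1 = 990, D2 = 2481, D3 = 624, D4 = 239) /
  (990 + 2481 + 624 + 239)

#' Specification of a synthetic genome
#'
#' Describes a genome tiled by consecutive TADs whose sizes follow a
#' log-normal distribution (fly-like median 70 kb by default; mouse-like
#' TADs have a median around 840 kb), each TAD carrying one epigenetic
#' class D1-D4 drawn from `class_proportions`, with per-class local
#' chromatin truth parameters used when sampling contact maps.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_bp Length of each chromosome in bp (truncated
#'   to a whole number of bins).
#' @param bin_size_kb Contact-map bin size in kb (default 5).
#' @param tad_median_kb Median TAD size in kb of the log-normal size
#'   distribution.
#' @param tad_sdlog Log-scale SD of TAD sizes.
#' @param class_proportions Named proportions for classes D1-D4 (must sum
#'   to 1).
#' @param class_params Named list of per-class truth vectors
#'   `c(K=, L=, S=)`.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 1,
                        chromosome_length_bp = 23e6,
                        bin_size_kb = 5,
                        tad_median_kb = 70,
                        tad_sdlog = 0.5,
                        class_proportions = .DEFAULT_CLASS_PROPORTIONS,
                        class_params = .DEFAULT_CLASS_PARAMS) {
  stopifnot(
    n_chromosomes >= 1, chromosome_length_bp > 0, bin_size_kb > 0,
    tad_median_kb > 0, tad_sdlog >= 0,
    !is.null(names(class_proportions)),
    abs(sum(class_proportions) - 1) < 1e-8,
    all(names(class_proportions) %in% names(class_params))
  )
  for (p in class_params) stopifnot(all(c("K", "L", "S") %in% names(p)),
                                    all(p[c("K", "L", "S")] > 0))
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length_bp = chromosome_length_bp,
      bin_size_kb = bin_size_kb,
      tad_median_kb = tad_median_kb,
      tad_sdlog = tad_sdlog,
      class_proportions = class_proportions,
      class_params = class_params
    ),
    class = "genome_spec"
  )
}

#' Simulate TAD and epigenetic-domain annotation tracks
#'
#' Tiles each chromosome with consecutive TADs whose sizes are drawn from
#' the log-normal distribution of the [genome_spec()] (rounded to whole
#' bins, minimum 2 bins) and assigns each TAD an epigenetic class from the
#' spec's proportions. Intervals are returned as `GRanges` (1-based,
#' closed ends, the Bioconductor convention; BED export is 0-based
#' half-open).
#'
#' @param spec A [genome_spec()].
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A list of class `synthetic_genome` with elements `tads` and
#'   `domains` (both `GRanges` with a `name` metadata column: TAD ids,
#'   resp. class labels D1-D4) and the `spec` itself.
#' @examples
#' g <- simulate_genome(genome_spec(chromosome_length_bp = 2e6), seed = 1)
#' g$tads
#' @export
simulate_genome <- function(spec = genome_spec(), seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  restore <- .local_seed(seed)
  if (!is.null(restore)) on.exit(restore(), add = TRUE)
  bin_bp <- spec$bin_size_kb * 1000
  n_bins_chr <- floor(spec$chromosome_length_bp / bin_bp)
  stopifnot(n_bins_chr >= 2)
  chroms <- sprintf("chrS%d", seq_len(spec$n_chromosomes))
  tad_list <- list()
  for (ci in seq_along(chroms)) {
    sizes_bins <- integer(0)
    while (sum(sizes_bins) < n_bins_chr) {
      draw_kb <- stats::rlnorm(64, meanlog = log(spec$tad_median_kb),
                               sdlog = spec$tad_sdlog)
      sizes_bins <- c(sizes_bins,
                      pmax(2L, as.integer(round(draw_kb / spec$bin_size_kb))))
    }
    cum <- cumsum(sizes_bins)
    k <- which(cum >= n_bins_chr)[1]
    sizes_bins <- sizes_bins[seq_len(k)]
    sizes_bins[k] <- sizes_bins[k] - (cum[k] - n_bins_chr)
    if (sizes_bins[k] < 2L && k > 1L) {
      # fold a truncated final stub into the previous TAD
      sizes_bins[k - 1L] <- sizes_bins[k - 1L] + sizes_bins[k]
      sizes_bins <- sizes_bins[-k]
    }
    ends <- cumsum(sizes_bins) * bin_bp
    starts0 <- c(0, ends[-length(ends)])
    classes <- sample(names(spec$class_proportions), length(sizes_bins),
                      replace = TRUE, prob = spec$class_proportions)
    tad_list[[ci]] <- data.frame(
      chrom = chroms[ci], start0 = starts0, end = ends,
      tad_id = sprintf("TAD_%s_%04d", chroms[ci], seq_along(sizes_bins)),
      class = classes, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, tad_list)
  gr <- function(label) {
    out <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start0 + 1, end = df$end)
    )
    S4Vectors::mcols(out)$name <- label
    out
  }
  structure(
    list(tads = gr(df$tad_id), domains = gr(df$class), spec = spec,
         seed = seed),
    class = "synthetic_genome"
  )
}

#' Sample a binned contact map from a synthetic genome
#'
#' Generates a normalized, binned contact map whose expected value for a
#' bin pair at genomic separation `s` inside one TAD follows the
#' unconstrained contact-frequency model with that TAD's epigenetic-class
#' truth parameters; pairs straddling a TAD border are additionally
#' multiplied by `attenuation` (cross-border contacts are strongly
#' depleted in Hi-C data). Observed values are either
#' `expected * exp(eps)` with log-normal noise (`mode = "lognormal"`) or
#' `Poisson(depth * expected) / depth` (`mode = "poisson"`, Hi-C-count
#' like; choose `depth` so that `depth * expected` is a sensible count).
#' Only pairs within `max_sep_kb` are materialized; self-contacts are
#' never included.
#'
#' @param genome A [simulate_genome()] result.
#' @param chrom Chromosome to sample (default: the genome's first).
#' @param max_sep_kb Largest bin-pair separation stored, kb.
#' @param attenuation Across-TAD-border multiplier in `[0, 1]`.
#' @param sigma_log Log-normal noise SD (ignored for `mode = "poisson"`);
#'   0 gives a noiseless map.
#' @param mode Noise model, `"lognormal"` or `"poisson"`.
#' @param depth Sequencing-depth scale for `mode = "poisson"`.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A [contact_map()] whose `truth` attribute records the
#'   generator parameters and the per-bin TAD id and class.
#' @examples
#' g <- simulate_genome(genome_spec(chromosome_length_bp = 1e6), seed = 1)
#' m <- simulate_contact_map(g, sigma_log = 0, seed = 1)
#' @export
simulate_contact_map <- function(genome, chrom = NULL, max_sep_kb = 400,
                                 attenuation = 0.1, sigma_log = 0.1,
                                 mode = c("lognormal", "poisson"),
                                 depth = 1e18, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"),
            attenuation >= 0, attenuation <= 1, sigma_log >= 0)
  mode <- match.arg(mode)
  spec <- genome$spec
  chroms <- as.character(unique(GenomicRanges::seqnames(genome$tads)))
  if (is.null(chrom)) chrom <- chroms[1]
  stopifnot(chrom %in% chroms)
  restore <- .local_seed(seed)
  if (!is.null(restore)) on.exit(restore(), add = TRUE)

  bin_kb <- spec$bin_size_kb
  bin_bp <- bin_kb * 1000
  sel <- as.character(GenomicRanges::seqnames(genome$tads)) == chrom
  tads <- genome$tads[sel]
  doms <- genome$domains[sel]
  n_bins <- sum(GenomicRanges::width(tads)) / bin_bp
  stopifnot(n_bins == round(n_bins))
  n_bins <- as.integer(n_bins)

  # per-bin TAD index and class (bins align with TAD borders by design)
  tad_starts0 <- GenomicRanges::start(tads) - 1
  bin_start0 <- (seq_len(n_bins) - 1) * bin_bp
  tad_idx <- findInterval(bin_start0, tad_starts0)
  bin_class <- S4Vectors::mcols(doms)$name[tad_idx]
  Kv <- vapply(spec$class_params, `[[`, numeric(1), "K")[bin_class]
  Lv <- vapply(spec$class_params, `[[`, numeric(1), "L")[bin_class]
  Sv <- vapply(spec$class_params, `[[`, numeric(1), "S")[bin_class]

  max_db <- min(n_bins - 1L, as.integer(max_sep_kb / bin_kb))
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (db in seq_len(max_db)) {
    i <- seq_len(n_bins - db)
    j <- i + db
    s_kb <- db * bin_kb
    mu <- contact_frequency(s_kb / Sv[i], K = Kv[i], L = Lv[i], S = Sv[i])
    cross <- tad_idx[i] != tad_idx[j]
    mu[cross] <- mu[cross] * attenuation
    val <- switch(mode,
      lognormal = mu * exp(stats::rnorm(length(mu), sd = sigma_log)),
      poisson = stats::rpois(length(mu), depth * mu) / depth
    )
    keep <- val > 0
    ii <- c(ii, i[keep]); jj <- c(jj, j[keep]); xx <- c(xx, val[keep])
  }
  map <- contact_map(
    data.frame(bin_i = ii - 1L, bin_j = jj - 1L, value = xx),
    chrom = chrom, bin_size_kb = bin_kb, n_bins = n_bins
  )
  attr(map, "truth") <- list(
    class_params = spec$class_params, attenuation = attenuation,
    sigma_log = if (mode == "lognormal") sigma_log else NA_real_,
    mode = mode, depth = if (mode == "poisson") depth else NA_real_,
    seed = seed, bin_tad = tad_idx, bin_class = bin_class
  )
  map
}

#' Write a JSON manifest of simulation ground truth
#'
#' Serializes the generator parameters (and seed) recorded on a simulated
#' object — a [simulate_3c_profile()] profile, [simulate_genome()] genome
#' or [simulate_contact_map()] map — so that downstream recovery analyses
#' are reproducible from files alone.
#'
#' @param x A simulated object carrying a `truth` attribute or `spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_simulation_manifest <- function(x, path) {
  payload <- if (inherits(x, "synthetic_genome")) {
    c(unclass(x$spec), list(seed = x$seed))
  } else {
    tr <- attr(x, "truth")
    if (is.null(tr)) stop("`x` carries no simulation ground truth")
    tr$bin_tad <- NULL # per-bin vectors stay in R; manifest holds parameters
    tr$bin_class <- NULL
    tr
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
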
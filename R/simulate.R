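# Synthetic endosperm data generator. All functions are deterministic given
# the configuration seed; each draws from its own derived seed so the
# generators can be called independently or through simulate_dataset().

.sim_seed <- function(config, offset) {
  # keep derived seeds well inside 32-bit integer range
  (config$seed %% 1000000L) * 1000L + offset
}

#' Generate a non-overlapping gene annotation
#'
#' Places `n_genes` non-overlapping genes of random length (uniform within
#' `gene_length_range`) on a single chromosome, with random strands and random
#' intergenic gaps. Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (half-open `[start, end)`).
#' @examples
#' ann <- generate_annotation(sim_config(n_genes = 20, chrom_length = 2e5))
#' all(ann$end > ann$start)
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 1L))
  n <- config$n_genes
  len <- sample.int(config$gene_length_range[2] - config$gene_length_range[1] + 1L,
                    n, replace = TRUE) + config$gene_length_range[1] - 1L
  free <- config$chrom_length - sum(as.numeric(len))
  if (free < n)
    stop("configuration error: chrom_length ", config$chrom_length,
         " too small to place ", n, " non-overlapping genes of total length ",
         sum(len), call. = FALSE)
  w <- stats::runif(n + 1L)
  gaps <- floor(w / sum(w) * free)
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, as.numeric(len[-n])))
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    chrom = config$chrom,
    start = as.numeric(starts),
    end = as.numeric(starts + len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Assign true imprinting classes and mark effects to simulated genes
#'
#' Splits genes into PEG / MEG / biallelic classes in the configured
#' proportions, attaches the class-level expected maternal read fraction, a
#' per-gene silencing-strength scale shared by all three marks, and the
#' per-allele mark effects. A configurable fraction of biallelic genes are
#' flagged as Polycomb targets carrying H3K27me3 on both alleles.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config A [sim_config()] object.
#' @return A `data.frame` (truth table) with one row per gene: `gene_id`,
#'   `class`, `maternal_fraction`, `effect_scale`, `prc2_target`, and the
#'   realized per-gene effects `chg_cc_effect`, `k27_mat_effect`,
#'   `k9_mat_effect`, `k27_pat_effect`.
#' @export
simulate_truth <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 2L))
  n <- nrow(annotation)
  counts <- diff(round(cumsum(c(0, config$class_fractions)) * n))
  classes <- sample(rep(names(config$class_fractions), counts))
  scale <- stats::runif(n, config$effect_scale_range[1], config$effect_scale_range[2])
  eff <- t(vapply(classes, function(cl) config$mark_effect[[cl]], numeric(3)))
  prc2 <- classes == "biallelic" &
    stats::runif(n) < config$prc2_target_fraction
  truth <- data.frame(
    gene_id = annotation$gene_id,
    class = classes,
    maternal_fraction = unname(config$maternal_fraction_by_class[classes]),
    effect_scale = scale,
    prc2_target = prc2,
    chg_cc_effect = eff[, "CHG_central_cell"] * scale,
    k27_mat_effect = eff[, "H3K27me3_mat"] * scale,
    k9_mat_effect = eff[, "H3K9me2_mat"] * scale,
    stringsAsFactors = FALSE
  )
  # Polycomb targets: H3K27me3 on both alleles, somewhat weaker than the
  # imprinted maternal-specific signal
  truth$k27_mat_effect <- pmax(truth$k27_mat_effect, ifelse(prc2, 1.5 * scale, 0))
  truth$k27_pat_effect <- ifelse(prc2, 1.5 * scale, 0)
  rownames(truth) <- NULL
  truth
}

.body_steps <- function(n_steps, step, start, end) {
  # indices of track steps fully attributable to [start, end)
  i0 <- floor(start / step) + 1L
  i1 <- ceiling(end / step)
  seq.int(max(1L, i0), min(n_steps, i1))
}

#' Simulate allele-resolved chromatin mark tracks and methylation calls
#'
#' Produces raw coverage tracks (fixed `track_step` bedGraph-style intervals)
#' for H3K27me3 and H3K9me2 on maternal and paternal alleles plus an H3
#' control per allele, and per-cytosine methylation calls per sequence context
#' for central cell, sperm, vegetative cell and the two endosperm alleles.
#' ChIP coverage is `h3 * 2^s` where the latent log2-ratio field `s` is
#' Gaussian background noise plus the per-gene maternal-allele effect inside
#' gene bodies; with `noise_sd = 0` the body log2 ratio equals the effect
#' exactly.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [simulate_truth()]; must cover every gene.
#' @param config A [sim_config()] object.
#' @return A list with elements `tracks` (nested list
#'   `[[mark]][[allele]]` of bedGraph-style data.frames `chrom`, `start`,
#'   `end`, `value`; marks `H3K27me3`, `H3K9me2`, `H3`) and `methylation`
#'   (list per source of CX-report-style data.frames `chrom`, `pos`, `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`).
#' @export
simulate_marks <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(annotation$gene_id %in% truth$gene_id))
    stop("truth table must cover every annotated gene", call. = FALSE)
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  set.seed(.sim_seed(config, 3L))

  step <- config$track_step
  n_steps <- as.integer(ceiling(config$chrom_length / step))
  starts <- (seq_len(n_steps) - 1L) * step
  ends <- pmin(starts + step, config$chrom_length)

  effect_field <- function(effcol) {
    s <- numeric(n_steps)
    pos <- which(effcol > 0)
    for (i in pos) {
      idx <- .body_steps(n_steps, step, annotation$start[i], annotation$end[i])
      s[idx] <- s[idx] + effcol[i]
    }
    s
  }
  make_track <- function(s) {
    noise <- if (config$noise_sd > 0) stats::rnorm(n_steps, 0, config$noise_sd) else 0
    val <- config$h3_level * 2^(s + noise)
    data.frame(chrom = config$chrom, start = starts, end = ends,
               value = val, stringsAsFactors = FALSE)
  }
  h3_track <- data.frame(chrom = config$chrom, start = starts, end = ends,
                         value = rep(config$h3_level, n_steps),
                         stringsAsFactors = FALSE)

  tracks <- list(
    H3K27me3 = list(
      maternal = make_track(effect_field(truth$k27_mat_effect)),
      paternal = make_track(effect_field(truth$k27_pat_effect))
    ),
    H3K9me2 = list(
      maternal = make_track(effect_field(truth$k9_mat_effect)),
      paternal = make_track(effect_field(numeric(nrow(truth))))
    ),
    H3 = list(maternal = h3_track, paternal = h3_track)
  )

  # per-cytosine methylation: sites of each context placed on a regular grid
  # within gene bodies (distinct phase per context so positions never collide)
  contexts <- c("CG", "CHG", "CHH")
  phase <- c(CG = 0L, CHG = 17L, CHH = 34L)
  site_list <- lapply(seq_len(nrow(annotation)), function(i) {
    lens <- annotation$end[i] - annotation$start[i]
    off <- seq.int(0L, lens - 1L, by = config$cytosine_spacing)
    do.call(rbind, lapply(contexts, function(ctx) {
      p <- annotation$start[i] + off + phase[[ctx]]
      p <- p[p < annotation$end[i]]
      data.frame(gene_idx = i, pos = p, context = ctx, stringsAsFactors = FALSE)
    }))
  })
  sites <- do.call(rbind, site_list)
  base_p <- config$methylation_baseline[sites$context]

  chg_boost <- function(extra) {
    # context-specific elevation applies to CHG sites only
    p <- base_p
    is_chg <- sites$context == "CHG"
    p[is_chg] <- pmin(0.98, p[is_chg] + extra[sites$gene_idx[is_chg]])
    p
  }
  draw_source <- function(p) {
    cov <- stats::rpois(nrow(sites), config$methylation_coverage)
    meth <- stats::rbinom(nrow(sites), cov, p)
    data.frame(
      chrom = config$chrom,
      pos = sites$pos,
      strand = annotation$strand[sites$gene_idx],
      count_methylated = meth,
      count_unmethylated = cov - meth,
      context = sites$context,
      stringsAsFactors = FALSE
    )
  }
  zero_extra <- numeric(nrow(annotation))
  methylation <- list(
    central_cell = draw_source(chg_boost(truth$chg_cc_effect)),
    sperm = draw_source(chg_boost(zero_extra)),
    vegetative_cell = draw_source(chg_boost(zero_extra)),
    endosperm_maternal = draw_source(chg_boost(0.8 * truth$chg_cc_effect)),
    endosperm_paternal = draw_source(chg_boost(zero_extra))
  )

  list(tracks = tracks, methylation = methylation)
}

#' Simulate reciprocal-cross allele-specific read counts
#'
#' Per gene, direction and replicate the total informative read count is
#' Poisson with mean `sequencing_depth`; maternal reads are a binomial (or
#' beta-binomial when `overdispersion > 0`) draw with success probability
#' `(1 - c) * f_class + c`, where `c` is the seed-coat contamination
#' proportion. The two reciprocal directions swap accession labels but
#' preserve parental roles, so the same per-gene maternal fraction applies to
#' both.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `gene_id`, `direction` (`"AxB"`,
#'   `"BxA"`), `replicate`, `maternal`, `paternal`.
#' @examples
#' cfg <- sim_config(n_genes = 10, chrom_length = 1e5, seed = 3)
#' ann <- generate_annotation(cfg)
#' cnt <- simulate_counts(ann, simulate_truth(ann, cfg), cfg)
#' head(cnt)
#' @export
simulate_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  set.seed(.sim_seed(config, 4L))
  n <- nrow(annotation)
  f_eff <- (1 - config$contamination) * truth$maternal_fraction + config$contamination
  out <- list()
  for (dir in c("AxB", "BxA")) {
    for (rep_i in seq_len(config$replicates_per_direction)) {
      total <- stats::rpois(n, config$sequencing_depth)
      p <- f_eff
      if (config$overdispersion > 0) {
        rho <- config$overdispersion
        shape <- (1 - rho) / rho
        a <- f_eff * shape
        b <- (1 - f_eff) * shape
        p <- stats::rbeta(n, pmax(a, 1e-12), pmax(b, 1e-12))
        p[f_eff == 0] <- 0
        p[f_eff == 1] <- 1
      }
      m <- stats::rbinom(n, total, p)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = annotation$gene_id,
        direction = dir,
        replicate = rep_i,
        maternal = m,
        paternal = total - m,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()], [simulate_truth()],
#' [simulate_marks()] and [simulate_counts()] from one configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `annotation`, `truth`, `marks`, `counts`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  annotation <- generate_annotation(config)
  truth <- simulate_truth(annotation, config)
  marks <- simulate_marks(annotation, truth, config)
  counts <- simulate_counts(annotation, truth, config)
  list(annotation = annotation, truth = truth, marks = marks,
       counts = counts, config = config)
}

#' Write a simulated dataset to standard file formats
#'
#' Writes the annotation as GFF3, coverage tracks as bedGraph (one file per
#' mark and allele), methylation calls as CX-report-style TSV (one file per
#' source), counts as TSV and the truth table as JSON.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulation <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "annotation.gff3")
  write_gene_gff3(dataset$annotation, f)
  files <- c(files, f)
  for (mark in names(dataset$marks$tracks)) {
    for (allele in names(dataset$marks$tracks[[mark]])) {
      f <- file.path(dir, sprintf("%s_%s.bedgraph", mark, allele))
      write_bedgraph(dataset$marks$tracks[[mark]][[allele]], f)
      files <- c(files, f)
    }
  }
  for (src in names(dataset$marks$methylation)) {
    f <- file.path(dir, sprintf("methylation_%s.tsv", src))
    utils::write.table(dataset$marks$methylation[[src]], f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "counts.tsv")
  utils::write.table(dataset$counts, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, f, digits = NA)
  files <- c(files, f)
  invisible(files)
}
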
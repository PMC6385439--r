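#' Simulation configuration for synthetic endosperm data
#'
#' Builds and validates the configuration object consumed by
#' [generate_annotation()], [simulate_truth()], [simulate_marks()] and
#' [simulate_counts()]. The defaults describe the study conditions the
#' package's analysis assumes: a triploid endosperm in which biallelically
#' expressed genes show a 2:1 maternal:paternal read ratio (maternal fraction
#' 2/3), a minority of imprinted genes (PEGs expressed mostly from the
#' paternal allele, MEGs from the maternal allele), maternal-allele elevation
#' of H3K27me3, H3K9me2 and central-cell CHG methylation on PEGs, and a
#' configurable admixture of purely maternal reads modeling seed-coat
#' contamination.
#'
#' @param n_genes Number of genes to simulate.
#' @param chrom Chromosome name used for all simulated features.
#' @param chrom_length Chromosome length in bp; must be large enough to place
#'   `n_genes` non-overlapping genes.
#' @param gene_length_range Length-2 integer vector, min and max gene length
#'   (bp).
#' @param class_fractions Named proportions over `PEG`, `MEG`, `biallelic`;
#'   must sum to 1 (tolerance 1e-9).
#' @param sequencing_depth Mean informative reads per gene, per cross
#'   direction and replicate (Poisson mean).
#' @param maternal_fraction_by_class Named vector of expected maternal read
#'   fractions per class. The biallelic entry must equal 2/3, the endosperm
#'   dosage expectation.
#' @param contamination Proportion in \[0,1\] of reads drawn from a purely
#'   maternal (seed-coat-like) source; the effective maternal success
#'   probability becomes `(1 - c) * f_class + c`.
#' @param mark_effect Named list (per class) of named numeric vectors giving
#'   the mean maternal-allele elevation of `CHG_central_cell` (methylation
#'   probability added to baseline), `H3K27me3_mat` and `H3K9me2_mat`
#'   (log2-ratio units over the H3 control).
#' @param noise_sd Standard deviation of the per-step log2-ratio mark noise.
#' @param replicates_per_direction Number of replicates per cross direction.
#' @param overdispersion Beta-binomial correlation rho for the maternal read
#'   split; 0 (default) gives a plain binomial split.
#' @param prc2_target_fraction Fraction of biallelic genes carrying H3K27me3
#'   on both alleles (Polycomb targets that are not imprinted).
#' @param effect_scale_range Per-gene silencing-strength multiplier range;
#'   one Uniform draw per gene scales all three mark effects jointly.
#' @param cytosine_spacing Mean spacing (bp) between simulated cytosines of
#'   one context inside gene bodies.
#' @param methylation_coverage Mean read coverage per cytosine (Poisson).
#' @param methylation_baseline Named baseline methylation probability per
#'   context (`CG`, `CHG`, `CHH`).
#' @param track_step Step size (bp) of the emitted raw coverage tracks.
#' @param h3_level H3 control coverage level (reads per step).
#' @param seed Integer seed; all generator functions are deterministic given
#'   the configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 50, chrom_length = 5e5, seed = 7)
#' cfg$class_fractions
#' @export
sim_config <- function(n_genes = 1000L,
                       chrom = "chr1",
                       chrom_length = 6e6,
                       gene_length_range = c(1000L, 3000L),
                       class_fractions = c(PEG = 0.10, MEG = 0.10, biallelic = 0.80),
                       sequencing_depth = 100,
                       maternal_fraction_by_class = c(PEG = 0.10, MEG = 0.95, biallelic = 2 / 3),
                       contamination = 0,
                       mark_effect = list(
                         PEG = c(CHG_central_cell = 0.45, H3K27me3_mat = 2.0, H3K9me2_mat = 1.5),
                         MEG = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0),
                         biallelic = c(CHG_central_cell = 0, H3K27me3_mat = 0, H3K9me2_mat = 0)
                       ),
                       noise_sd = 0.3,
                       replicates_per_direction = 2L,
                       overdispersion = 0,
                       prc2_target_fraction = 0.15,
                       effect_scale_range = c(0.6, 1.4),
                       cytosine_spacing = 50L,
                       methylation_coverage = 20,
                       methylation_baseline = c(CG = 0.20, CHG = 0.05, CHH = 0.03),
                       track_step = 50L,
                       h3_level = 100,
                       seed = 1L) {
  classes <- c("PEG", "MEG", "biallelic")
  marks <- c("CHG_central_cell", "H3K27me3_mat", "H3K9me2_mat")

  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("`n_genes` must be a positive integer", call. = FALSE)
  if (length(gene_length_range) != 2L || any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2])
    stop("`gene_length_range` must be an increasing pair of positive lengths",
         call. = FALSE)
  if (!all(classes %in% names(class_fractions)))
    stop("`class_fractions` must be named over PEG, MEG, biallelic", call. = FALSE)
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must be non-negative and sum to 1", call. = FALSE)
  if (!all(classes %in% names(maternal_fraction_by_class)))
    stop("`maternal_fraction_by_class` must be named over PEG, MEG, biallelic",
         call. = FALSE)
  maternal_fraction_by_class <- maternal_fraction_by_class[classes]
  if (any(maternal_fraction_by_class < 0) || any(maternal_fraction_by_class > 1))
    stop("maternal fractions must lie in [0, 1]", call. = FALSE)
  if (abs(maternal_fraction_by_class[["biallelic"]] - 2 / 3) > 1e-9)
    stop("the biallelic maternal fraction is the endosperm dosage expectation ",
         "and must equal 2/3", call. = FALSE)
  if (contamination < 0 || contamination > 1)
    stop("`contamination` must lie in [0, 1]", call. = FALSE)
  if (!all(classes %in% names(mark_effect)))
    stop("`mark_effect` must provide an entry for each class (PEG, MEG, biallelic)",
         call. = FALSE)
  for (cl in classes) {
    if (!all(marks %in% names(mark_effect[[cl]])))
      stop("`mark_effect[['", cl, "']]` must name all of: ",
           paste(marks, collapse = ", "), call. = FALSE)
  }
  if (overdispersion < 0 || overdispersion >= 1)
    stop("`overdispersion` (beta-binomial rho) must lie in [0, 1)", call. = FALSE)
  if (sequencing_depth <= 0) stop("`sequencing_depth` must be positive", call. = FALSE)
  if (!all(c("CG", "CHG", "CHH") %in% names(methylation_baseline)))
    stop("`methylation_baseline` must be named over CG, CHG, CHH", call. = FALSE)

  cfg <- list(
    n_genes = n_genes,
    chrom = chrom,
    chrom_length = as.numeric(chrom_length),
    gene_length_range = as.integer(gene_length_range),
    class_fractions = class_fractions,
    sequencing_depth = sequencing_depth,
    maternal_fraction_by_class = maternal_fraction_by_class,
    contamination = contamination,
    mark_effect = lapply(mark_effect[classes], function(x) x[marks]),
    noise_sd = noise_sd,
    replicates_per_direction = as.integer(replicates_per_direction),
    overdispersion = overdispersion,
    prc2_target_fraction = prc2_target_fraction,
    effect_scale_range = effect_scale_range,
    cytosine_spacing = as.integer(cytosine_spacing),
    methylation_coverage = methylation_coverage,
    methylation_baseline = methylation_baseline[c("CG", "CHG", "CHH")],
    track_step = as.integer(track_step),
    h3_level = h3_level,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes on", x$chrom,
      sprintf("(%.3g bp)", x$chrom_length), "\n")
  cat("  class fractions:",
      paste(sprintf("%s=%.2f", names(x$class_fractions), x$class_fractions),
            collapse = " "), "\n")
  cat("  depth:", x$sequencing_depth, " contamination:", x$contamination,
      " replicates/direction:", x$replicates_per_direction, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
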
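#' Simulation parameters for the synthetic vent metagenome
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' statistical structure the analysis assumes: hosts carrying CRISPR arrays
#' whose repeats come from a small reference set (29-31 nt), spacers with a
#' median length of 37 nt (range 30-50), MGE families sharing diverged
#' protein-coding core modules, a controlled fraction of complete genomes
#' with direct or inverted terminal repeats (20-60 bp), protospacers planted
#' at controlled nucleotide identity, and i.i.d. random decoy contigs.
#'
#' @param seed integer; the single seed from which all randomness flows.
#' @param n_hosts number of host genomes.
#' @param n_mge_families number of MGE families.
#' @param mges_per_family members per family.
#' @param repeat_length_window allowed reference-repeat lengths (nt).
#' @param n_reference_repeats size of the reference repeat set.
#' @param spacer_length_range spacer length bounds (nt).
#' @param spacer_length_median mode/median of the discretized spacer length
#'   distribution (weights proportional to a normal density, sd 4 nt).
#' @param protospacer_identity_range planted protospacer identity bounds; a
#'   planted hit never falls outside this range.
#' @param frac_complete_mges fraction of members per family carrying a
#'   terminal repeat; the count per family is fixed at
#'   `round(frac * members)` so every family has a predictable number of
#'   complete genomes.
#' @param terminal_repeat_length_range DTR/ITR length bounds (nt).
#' @param contig_fragmentation mean fragment length (nt) used when tiling
#'   incomplete MGEs and host genomes into contigs.
#' @param n_decoys number of unrelated random contigs.
#' @param gc_content background GC fraction.
#' @param n_core_modules core protein modules shared by a family.
#' @param n_accessory member-specific accessory ORFs.
#' @param core_identity_range target pairwise amino-acid identity range for
#'   core modules; realized pairwise identity is additionally kept >= 0.40
#'   by bounded resampling.
#' @param gene_length_codons ORF length bounds (codons, excluding stop).
#' @param intergenic_length_range intergenic spacer bounds (nt).
#' @param arrays_per_host_range CRISPR arrays per host genome.
#' @param repeats_per_array_range repeat instances per array.
#' @param frac_mge_derived minimum fraction of spacers per array drawn from
#'   the MGE pool (the remainder are random "dark" spacers).
#' @param repeat_variant_prob probability that an array uses a reference
#'   repeat carrying one substitution (the same variant in every instance).
#' @param host_length host genome background length (nt).
#' @param decoy_length_range decoy contig length bounds (nt).
#'
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(seed = 1L,
                       n_hosts = 3L,
                       n_mge_families = 5L,
                       mges_per_family = 4L,
                       repeat_length_window = c(29L, 31L),
                       n_reference_repeats = 8L,
                       spacer_length_range = c(30L, 50L),
                       spacer_length_median = 37L,
                       protospacer_identity_range = c(0.90, 1.00),
                       frac_complete_mges = 0.5,
                       terminal_repeat_length_range = c(20L, 60L),
                       contig_fragmentation = 3500L,
                       n_decoys = 450L,
                       gc_content = 0.45,
                       n_core_modules = 12L,
                       n_accessory = 2L,
                       core_identity_range = c(0.45, 0.90),
                       gene_length_codons = c(90L, 150L),
                       intergenic_length_range = c(25L, 55L),
                       arrays_per_host_range = c(1L, 3L),
                       repeats_per_array_range = c(12L, 24L),
                       frac_mge_derived = 0.8,
                       repeat_variant_prob = 0.3,
                       host_length = 30000L,
                       decoy_length_range = c(600L, 8000L)) {
  p <- list(
    seed = as.integer(seed), n_hosts = as.integer(n_hosts),
    n_mge_families = as.integer(n_mge_families),
    mges_per_family = as.integer(mges_per_family),
    repeat_length_window = as.integer(repeat_length_window),
    n_reference_repeats = as.integer(n_reference_repeats),
    spacer_length_range = as.integer(spacer_length_range),
    spacer_length_median = as.integer(spacer_length_median),
    protospacer_identity_range = as.numeric(protospacer_identity_range),
    frac_complete_mges = as.numeric(frac_complete_mges),
    terminal_repeat_length_range = as.integer(terminal_repeat_length_range),
    contig_fragmentation = as.integer(contig_fragmentation),
    n_decoys = as.integer(n_decoys),
    gc_content = as.numeric(gc_content),
    n_core_modules = as.integer(n_core_modules),
    n_accessory = as.integer(n_accessory),
    core_identity_range = as.numeric(core_identity_range),
    gene_length_codons = as.integer(gene_length_codons),
    intergenic_length_range = as.integer(intergenic_length_range),
    arrays_per_host_range = as.integer(arrays_per_host_range),
    repeats_per_array_range = as.integer(repeats_per_array_range),
    frac_mge_derived = as.numeric(frac_mge_derived),
    repeat_variant_prob = as.numeric(repeat_variant_prob),
    host_length = as.integer(host_length),
    decoy_length_range = as.integer(decoy_length_range)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  fr <- c("protospacer_identity_range", "frac_complete_mges",
          "frac_mge_derived", "repeat_variant_prob", "gc_content",
          "core_identity_range")
  for (f in fr) {
    v <- p[[f]]
    if (any(v < 0 | v > 1)) stop("parameter '", f, "' must lie in [0,1]")
  }
  if (p$repeat_length_window[1] < 29L || p$repeat_length_window[2] > 31L) {
    stop("repeat_length_window must stay within [29, 31] nt")
  }
  rng2 <- function(x) length(x) == 2L && x[1] <= x[2]
  stopifnot(
    rng2(p$repeat_length_window), rng2(p$spacer_length_range),
    rng2(p$protospacer_identity_range), rng2(p$terminal_repeat_length_range),
    rng2(p$core_identity_range), rng2(p$gene_length_codons),
    rng2(p$intergenic_length_range), rng2(p$arrays_per_host_range),
    rng2(p$repeats_per_array_range), rng2(p$decoy_length_range),
    p$n_hosts >= 1L, p$n_mge_families >= 1L, p$mges_per_family >= 1L,
    p$n_decoys >= 0L, p$repeats_per_array_range[1] >= 3L,
    p$terminal_repeat_length_range[1] >= 20L,
    p$gene_length_codons[1] >= 60L
  )
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic vent metagenome parameters (seed ", x$seed, ")\n", sep = "")
  cat("  hosts: ", x$n_hosts, "  MGE families: ", x$n_mge_families,
      " x ", x$mges_per_family, " members\n", sep = "")
  cat("  decoys: ", x$n_decoys, "  fragment mean: ",
      x$contig_fragmentation, " nt\n", sep = "")
  invisible(x)
}

# flat key=value config file -> sim_params override list
read_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (x in kv) {
    if (length(x) != 2L) stop("malformed config line: ", paste(x, collapse = "="))
    val <- trimws(x[2])
    vals <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[trimws(x[1])]] <- if (anyNA(num)) vals else num
  }
  out
}
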
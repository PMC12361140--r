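# Shared fixture builders for the test suite. Everything is generated in code
# at test time; no stored data files.

# one-strain config with a given true slope; kinetics overrides merge into the
# plate-reader defaults
one_strain_config <- function(seed = 1, true_slope = 2.412e-4,
                              sigma_od = 0.002, kinetics = list()) {
  kin <- utils::modifyList(
    list(m = 1, t_off = 10, d = 5, sigma_od = sigma_od, t_max = 240, step = 5),
    kinetics)
  synth_config(
    seed = seed,
    strains = tibble::tibble(
      strain_id = "s1", compartment = "A", archetype = "downstream_orf",
      fold_reference = 1, fold_starvation = 1, fold_stationary = 1,
      true_slope = true_slope, popin_fraction = 0.5, position = 1000L,
      nearest_locus = "gene1", nearest_cpm = 10, essentiality = 1L),
    kinetics = kin)
}

# curve sampled directly from the model (bypasses the generator) for unit
# tests that need full control of the noise stream
model_curve <- function(sl, m = 1, t_off = 10, d = 5, sigma = 0,
                        times = seq(0, 240, 5), seed = NULL,
                        strain = "s", condition = "c", bio = 1, tech = 1) {
  mu <- eval_model(c(sl = sl, m = m, t_off = t_off, d = d), times)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (sigma > 0) stats::rnorm(length(times), 0, sigma) else 0
  kinetic_curve(strain, condition, bio, tech, times, mu + noise)
}

# minimal gene neighbourhood around a site at `pos`
flank_genes <- function(pos, left_strand, right_strand,
                        left_op = NA_character_, right_op = NA_character_,
                        gap = 100) {
  tibble::tibble(
    locus_tag = c("gL", "gR"),
    start = as.integer(c(pos - 1000, pos + gap)),
    end = as.integer(c(pos - gap, pos + 1000)),
    strand = c(left_strand, right_strand),
    expression_cpm = c(50, 5),
    essentiality_rank = c(NA_integer_, NA_integer_),
    operon_id = c(left_op, right_op))
}

no_terminators <- function() {
  tibble::tibble(position = integer(), strand = character())
}

# hand-built CT table: one row per technical replicate, exact values
ct_rows <- function(strain, condition, role, bio, cts) {
  tibble::tibble(strain_id = strain, condition = condition, gene_role = role,
                 bio_rep = bio, tech_rep = seq_along(cts), ct = cts)
}
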
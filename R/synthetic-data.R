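#' Derive a deterministic substream seed
#'
#' Expands one global seed into independent per-stream seeds (CT table,
#' kinetic plate, CFU counts, ...) so that adding a generator never perturbs
#' the draws of another. Pure integer arithmetic below 2^31.
#'
#' @param seed Global integer seed.
#' @param stream Small integer stream index (1 = CT, 2 = kinetics, 3 = CFU).
#' @return Integer seed.
#' @export
stream_seed <- function(seed, stream) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(stream) * 1000003) %% m)
}

#' Synthetic study configuration
#'
#' Bundles every ground-truth parameter the generators consume: the per-strain
#' table (compartment, transcription fold changes per condition, true
#' conversion slope, site topology archetype, pop-in fraction, genomic
#' position and nearest-gene annotation) plus noise levels, the plate-reader
#' grid and the toy genome geometry.
#'
#' @param seed Global seed.
#' @param strains Tibble; see [study_mimic_config()] for the expected columns.
#' @param ct_base_reference Reference-gene base CT (cycles).
#' @param ct_base_target Target-gene base CT at the baseline expression unit;
#'   the default keeps CT above 8 cycles for fold changes up to 60.
#' @param sigma_tech_ct,sigma_bio_ct Technical / biological CT noise (cycles).
#' @param n_bio_ct,n_tech_ct Replicate structure of the CT table for
#'   replicated conditions.
#' @param kinetics List with `m`, `t_off`, `d`, `sigma_od`, `t_max`, `step`.
#' @param n_bio_kin,n_tech_kin Replicate structure of the kinetic plate.
#' @param cfu_total Screened CFUs per strain (scalar or per-strain vector).
#' @param genome List with `length`, `origins` (tibble `name`, `position`) and
#'   `compartments` (tibble `start`, `end`, `label`).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, strains,
                         ct_base_reference = 18, ct_base_target = 26,
                         sigma_tech_ct = 0.15, sigma_bio_ct = 0.2,
                         n_bio_ct = 3, n_tech_ct = 3,
                         kinetics = list(m = 1, t_off = 10, d = 5,
                                         sigma_od = 0.002, t_max = 240, step = 5),
                         n_bio_kin = 1, n_tech_kin = 3,
                         cfu_total = 20000,
                         genome = NULL) {
  stopifnot(is.data.frame(strains), nrow(strains) >= 1,
            sigma_tech_ct >= 0, sigma_bio_ct >= 0,
            all(strains$fold_reference > 0), all(strains$true_slope > 0),
            kinetics$sigma_od >= 0)
  archetypes <- c("divergent_promoters", "downstream_orf", "inter_operonic",
                  "pre_terminator", "convergent_3prime", "intra_gene")
  if (!all(strains$archetype %in% archetypes))
    stop(sprintf("unknown site archetype(s): %s",
                 paste(setdiff(strains$archetype, archetypes), collapse = ", ")))
  if (!is.null(genome)) {
    if (any(strains$position < 1 | strains$position > genome$length))
      stop("strain site position outside the genome")
  }
  structure(list(seed = as.integer(seed), strains = strains,
                 ct_base_reference = ct_base_reference,
                 ct_base_target = ct_base_target,
                 sigma_tech_ct = sigma_tech_ct, sigma_bio_ct = sigma_bio_ct,
                 n_bio_ct = n_bio_ct, n_tech_ct = n_tech_ct,
                 kinetics = kinetics,
                 n_bio_kin = n_bio_kin, n_tech_kin = n_tech_kin,
                 cfu_total = cfu_total, genome = genome),
            class = "synth_config")
}

#' Study-mimic configuration
#'
#' The default synthetic study: nine knock-in strains whose ground truths are
#' pinned to the published per-strain values where available (reference-
#' condition transcription fold changes relative to the arlJ baseline,
#' compartment-mean conversion slopes, compartment-mean pop-in fractions,
#' Fig.-3-style site topologies and Table-1-style genome geometry); values
#' the study does not print per strain are fixed plausible choices documented
#' in the methods vignette.
#'
#' Conditions generated: `reference_growth` and `stationary` with three
#' biological replicates, `starvation` with one (the study's starvation
#' samples were unreplicated).
#'
#' @param seed Global seed.
#' @return A [synth_config()].
#' @export
study_mimic_config <- function(seed = 1) {
  strains <- tibble::tribble(
    ~strain_id, ~compartment, ~archetype,            ~fold_reference, ~fold_starvation, ~fold_stationary, ~true_slope, ~popin_fraction, ~position, ~nearest_locus, ~nearest_cpm, ~essentiality,
    "clsN",     "A",          "divergent_promoters", 1.88,            1.0,              1.0,              2.90e-4,     0.34,            32281L,    "Saci_0046",    1.955,        3L,
    "ccc1",     "A",          "inter_operonic",      5.2,             1.5,              1.4,              2.00e-4,     0.88,            235243L,   "Saci_0278",    55.012,       13L,
    "sdhC",     "B",          "downstream_orf",      3.0,             2.0,              1.8,              1.60e-4,     0.26,            278353L,   "Saci_0325",    129.5,        20L,
    "vapC",     "A",          "pre_terminator",      6.2,             0.5,              0.6,              2.70e-4,     0.52,            394047L,   "Saci_0467",    1.47,         23L,
    "l2p",      "A",          "downstream_orf",      2.6,             0.8,              0.9,              1.80e-4,     0.42,            473288L,   "Saci_0594",    53.09,        2L,
    "acad",     "B",          "divergent_promoters", 1.86,            1.7,              1.0,              1.50e-4,     0.14,            928402L,   "Saci_1123",    56.12,        43L,
    "arlJ",     "B",          "convergent_3prime",   1.0,             1.0,              1.0,              1.20e-4,     0.12,            987911L,   "Saci_1172",    18.05,        NA_integer_,
    "arlB",     "B",          "downstream_orf",      3.4,             2.5,              2.0,              1.376e-4,   0.36,            993346L,   "Saci_1178",    35.18,        11L,
    "slaA",     "A",          "downstream_orf",      55,              0.5,              0.5,              2.66e-4,    0.64,            2199897L,  "Saci_2355",    11.554,       7L)

  genome <- list(
    length = 2225959L,
    origins = tibble::tibble(name = c("oriC1", "oriC2", "oriC3"),
                             position = c(556450L, 2225941L, 1225700L)),
    compartments = tibble::tibble(
      start = c(1L, 270001L, 330001L, 850001L, 2150000L),
      end = c(270000L, 330000L, 850000L, 2149999L, 2225959L),
      label = c("A", "B", "A", "B", "A")))

  synth_config(seed = seed, strains = strains, genome = genome)
}

#' Generate a synthetic qRT-PCR CT table
#'
#' For each strain, condition and biological replicate, reference-gene CT is
#' `ct_base_reference + bio_effect + tech_noise` and target CT is
#' `ct_base_target - log2(expression) + bio_effect + tech_noise'`, where the
#' expression level is the configured reference-condition fold change times
#' the condition-regulation factor, and the biological effect (sample-loading
#' covariance) is shared between target and reference so that delta CT
#' cancels it. Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return Tibble of CT records (`strain_id`, `condition`, `gene_role`,
#'   `bio_rep`, `tech_rep`, `ct`).
#' @export
gen_ct_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, 1L))
  conds <- tibble::tibble(
    condition = c("reference_growth", "starvation", "stationary"),
    n_bio = c(config$n_bio_ct, 1L, config$n_bio_ct))

  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    cond <- conds$condition[ci]
    fold_col <- c(reference_growth = "fold_reference",
                  starvation = "fold_starvation",
                  stationary = "fold_stationary")[[cond]]
    for (si in seq_len(nrow(config$strains))) {
      st <- config$strains[si, ]
      expr <- st$fold_reference *
        (if (cond == "reference_growth") 1 else st[[fold_col]] )
      for (b in seq_len(conds$n_bio[ci])) {
        bio_eff <- stats::rnorm(1, 0, config$sigma_bio_ct)
        for (role in c("reference", "target")) {
          base <- if (role == "reference") config$ct_base_reference
                  else config$ct_base_target - log2(expr)
          tech <- stats::rnorm(config$n_tech_ct, 0, config$sigma_tech_ct)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            strain_id = st$strain_id, condition = cond, gene_role = role,
            bio_rep = b, tech_rep = seq_len(config$n_tech_ct),
            ct = base + bio_eff + tech)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic kinetic plate
#'
#' Samples ONPG conversion curves from [eval_model()] at each strain's true
#' slope plus i.i.d. Gaussian noise on the configured plate-reader grid
#' (default 0-240 min in 5-min steps, 49 points). Deterministic given the
#' config seed.
#'
#' @param config A [synth_config()].
#' @return List of [kinetic_curve()] objects (condition `reference_growth`).
#' @export
gen_kinetic_plate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, 2L))
  k <- config$kinetics
  tt <- seq(0, k$t_max, by = k$step)
  curves <- list()
  for (si in seq_len(nrow(config$strains))) {
    st <- config$strains[si, ]
    mu <- eval_model(c(sl = st$true_slope, m = k$m, t_off = k$t_off, d = k$d), tt)
    for (b in seq_len(config$n_bio_kin)) {
      for (tr in seq_len(config$n_tech_kin)) {
        curves[[length(curves) + 1L]] <- kinetic_curve(
          st$strain_id, "reference_growth", b, tr, tt,
          mu + stats::rnorm(length(tt), 0, k$sigma_od))
      }
    }
  }
  curves
}

# gene neighbourhoods realising each site topology archetype; coordinates are
# offsets around the site position
.archetype_genes <- function(st, genome_length) {
  pos <- st$position
  tag <- st$nearest_locus
  cpm <- st$nearest_cpm
  ess <- st$essentiality
  alt_tag <- paste0(tag, "n")  # generic neighbour
  g <- function(locus, start, end, strand, cpm_g, op = NA_character_,
                ess_g = NA_integer_)
    tibble::tibble(locus_tag = locus, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   expression_cpm = cpm_g, essentiality_rank = ess_g,
                   operon_id = op)
  terms <- tibble::tibble(position = integer(), strand = character())
  genes <- switch(st$archetype,
    divergent_promoters = dplyr::bind_rows(
      g(tag, pos - 1200, pos - 150, "-", cpm, ess_g = ess),
      g(alt_tag, pos + 150, pos + 1200, "+", 5)),
    downstream_orf = dplyr::bind_rows(
      g(tag, pos - 1200, pos - 60, "+", cpm, ess_g = ess),
      g(alt_tag, pos + 400, pos + 1400, "+", 5)),
    inter_operonic = dplyr::bind_rows(
      g(tag, pos - 1100, pos - 100, "+", cpm, op = paste0("op_", st$strain_id),
        ess_g = ess),
      g(alt_tag, pos + 100, pos + 1100, "+", cpm, op = paste0("op_", st$strain_id))),
    pre_terminator = {
      terms <- tibble::tibble(position = as.integer(pos + 120), strand = "+")
      dplyr::bind_rows(
        g(tag, pos - 1200, pos - 150, "+", cpm, ess_g = ess),
        g(alt_tag, pos + 300, pos + 1300, "+", 5))
    },
    convergent_3prime = dplyr::bind_rows(
      g(tag, pos - 1100, pos - 80, "+", cpm, ess_g = ess),
      g(alt_tag, pos + 150, pos + 1150, "-", 8)),
    intra_gene = g(tag, pos - 500, pos + 500, "+", cpm, ess_g = ess))
  genes$start <- ((genes$start - 1L) %% genome_length) + 1L
  genes$end <- ((genes$end - 1L) %% genome_length) + 1L
  list(genes = genes, terminators = terms)
}

#' Generate the toy genome fixture
#'
#' Builds a small circular genome realising each configured strain's site
#' topology archetype: per strain a gene neighbourhood (divergent promoters,
#' a high-expression upstream ORF, operonic co-directional genes, a
#' pre-terminator context, converging 3' ends, or an intragenic site),
#' compartment intervals consistent with the configured labels and the
#' replication origins. Optionally writes GFF3 / BED / TSV files that
#' round-trip through the package readers. This fixture is synthetic: its
#' geometry emulates the published site table but is generated, not measured.
#'
#' @param config A [synth_config()] with a `genome` element.
#' @param dir Optional output directory; when given, writes `genes.gff3`,
#'   `compartments.bed`, `origins.tsv`, `sites.tsv`.
#' @return List with `genes`, `terminators`, `origins`, `compartments`,
#'   `sites`, `genome_length` (and `paths` when files were written).
#' @export
gen_genome_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"), !is.null(config$genome))
  gl <- config$genome$length
  parts <- lapply(seq_len(nrow(config$strains)), function(i)
    .archetype_genes(config$strains[i, ], gl))
  genes <- dplyr::bind_rows(lapply(parts, `[[`, "genes"))
  terminators <- dplyr::bind_rows(lapply(parts, `[[`, "terminators"))
  sites <- tibble::tibble(name = config$strains$strain_id,
                          position = as.integer(config$strains$position),
                          cassette_strand = "+")
  out <- list(genes = genes, terminators = terminators,
              origins = config$genome$origins,
              compartments = config$genome$compartments,
              sites = sites, genome_length = gl)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genes = file.path(dir, "genes.gff3"),
                  compartments = file.path(dir, "compartments.bed"),
                  origins = file.path(dir, "origins.tsv"),
                  sites = file.path(dir, "sites.tsv"))
    write_genes_gff3(genes, terminators, paths$genes)
    write_compartments_bed(config$genome$compartments, paths$compartments)
    readr::write_tsv(config$genome$origins, paths$origins)
    readr::write_tsv(sites, paths$sites)
    out$paths <- paths
  }
  out
}

#' Generate synthetic pop-in screening counts
#'
#' Blue CFU counts are binomial draws at each strain's configured pop-in
#' fraction out of the configured total screened CFUs. Deterministic given
#' the config seed.
#'
#' @param config A [synth_config()].
#' @return Tibble with `strain_id`, `blue_cfu`, `total_cfu`.
#' @export
gen_cfu_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, 3L))
  totals <- rep_len(config$cfu_total, nrow(config$strains))
  tibble::tibble(
    strain_id = config$strains$strain_id,
    blue_cfu = stats::rbinom(nrow(config$strains), totals,
                             config$strains$popin_fraction / 100),
    total_cfu = as.integer(totals))
}
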
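#' @importFrom rlang .data
NULL

.check_header <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s; expected header `%s`",
                 path, paste(missing, collapse = ", "),
                 paste(expected, collapse = ",")))
  invisible(df)
}

.read_delim_checked <- function(path, delim, expected) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0) stop(sprintf("empty file: %s", path))
  .check_header(df, expected, path)
  tibble::as_tibble(df[expected])
}

#' Read a plate-reader CSV of ONPG time series
#'
#' Long format with header
#' `strain,condition,bio_rep,tech_rep,time_min,od410`.
#'
#' @param path File path.
#' @return List of [kinetic_curve()] objects.
#' @export
read_plate_csv <- function(path) {
  df <- .read_delim_checked(path, ",", c("strain", "condition", "bio_rep",
                                         "tech_rep", "time_min", "od410"))
  grp <- split(df, paste(df$strain, df$condition, df$bio_rep, df$tech_rep,
                         sep = "\r"))
  lapply(unname(grp), function(g) {
    g <- g[order(g$time_min), ]
    kinetic_curve(g$strain[1], g$condition[1], g$bio_rep[1], g$tech_rep[1],
                  g$time_min, g$od410)
  })
}

#' Write a plate of kinetic curves to CSV
#'
#' @param curves List of [kinetic_curve()] objects.
#' @param path Output path.
#' @export
write_plate_csv <- function(curves, path) {
  df <- dplyr::bind_rows(lapply(curves, function(cu)
    tibble::tibble(strain = cu$strain_id, condition = cu$condition,
                   bio_rep = cu$bio_rep, tech_rep = cu$tech_rep,
                   time_min = cu$times, od410 = cu$od410)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a qRT-PCR CT table CSV
#'
#' Header `strain,condition,gene_role,bio_rep,tech_rep,ct`.
#'
#' @param path File path.
#' @return Tibble of CT records with package-internal column names.
#' @export
read_ct_csv <- function(path) {
  df <- .read_delim_checked(path, ",", c("strain", "condition", "gene_role",
                                         "bio_rep", "tech_rep", "ct"))
  dplyr::rename(df, strain_id = "strain")
}

#' Write a CT table CSV
#' @param ct_table Tibble as from [gen_ct_table()].
#' @param path Output path.
#' @export
write_ct_csv <- function(ct_table, path) {
  readr::write_csv(dplyr::rename(ct_table, strain = "strain_id"), path)
  invisible(path)
}

#' Read target sites TSV (`name,position[,cassette_strand]`)
#' @param path File path.
#' @return Tibble with `name`, `position`, `cassette_strand`.
#' @export
read_sites_tsv <- function(path) {
  df <- .read_delim_checked(path, "\t", c("name", "position"))
  df$position <- as.integer(df$position)
  if (!"cassette_strand" %in% names(df)) df$cassette_strand <- "+"
  df
}

#' Read replication origins TSV (`name,position`)
#' @param path File path.
#' @return Tibble with `name`, `position`.
#' @export
read_origins_tsv <- function(path) {
  df <- .read_delim_checked(path, "\t", c("name", "position"))
  df$position <- as.integer(df$position)
  df
}

#' Read chromatin compartment intervals from BED
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' inclusive convention at this boundary; the BED name field carries the
#' compartment label.
#'
#' @param path File path.
#' @return Tibble with 1-based `start`, `end` and `label`.
#' @export
read_compartments_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) stop(sprintf("empty file: %s", path))
  tibble::tibble(start = as.integer(GenomicRanges::start(gr)),
                 end = as.integer(GenomicRanges::end(gr)),
                 label = as.character(gr$name))
}

#' Write compartment intervals to BED
#' @param compartments Tibble with 1-based `start`, `end`, `label`.
#' @param path Output path.
#' @param chrom Chromosome name to use.
#' @export
write_compartments_bed <- function(compartments, path, chrom = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = compartments$start,
                              end = compartments$end),
    name = compartments$label)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene and terminator annotation from GFF3
#'
#' Gene features must carry a `locus_tag` attribute and may carry
#' `operon_id`, `expression_cpm` and `essentiality_rank`; `terminator`
#' features need only coordinates and strand. Gene records lacking a
#' `locus_tag` are rejected with their file line numbers.
#'
#' @param path File path.
#' @return List with `genes` and `terminators` tibbles.
#' @export
read_genes_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "GFF3")
  if (length(gr) == 0) stop(sprintf("empty file: %s", path))
  md <- S4Vectors::mcols(gr)
  is_gene <- as.character(md$type) == "gene"
  lt <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag)
        else rep(NA_character_, length(gr))
  if (any(is_gene & is.na(lt))) {
    lines <- readLines(path)
    feature_lines <- which(!startsWith(lines, "#") & nzchar(lines))
    bad <- feature_lines[which(is_gene & is.na(lt))]
    stop(sprintf("%s: gene feature(s) missing locus_tag at line(s) %s",
                 path, paste(bad, collapse = ", ")))
  }
  num_or_na <- function(col) {
    if (col %in% names(md)) suppressWarnings(as.numeric(as.character(md[[col]])))
    else rep(NA_real_, length(gr))
  }
  chr_or_na <- function(col) {
    if (col %in% names(md)) as.character(md[[col]])
    else rep(NA_character_, length(gr))
  }
  genes <- tibble::tibble(
    locus_tag = lt[is_gene],
    start = as.integer(GenomicRanges::start(gr[is_gene])),
    end = as.integer(GenomicRanges::end(gr[is_gene])),
    strand = as.character(GenomicRanges::strand(gr[is_gene])),
    expression_cpm = num_or_na("expression_cpm")[is_gene],
    essentiality_rank = as.integer(num_or_na("essentiality_rank")[is_gene]),
    operon_id = chr_or_na("operon_id")[is_gene])
  is_term <- as.character(md$type) == "terminator"
  terminators <- tibble::tibble(
    position = as.integer(GenomicRanges::start(gr[is_term])),
    strand = as.character(GenomicRanges::strand(gr[is_term])))
  list(genes = genes, terminators = terminators)
}

#' Write gene and terminator annotation to GFF3
#' @param genes Gene tibble (see [classify_site_context()]).
#' @param terminators Terminator tibble (may be empty or `NULL`).
#' @param path Output path.
#' @param chrom Chromosome name to use.
#' @export
write_genes_gff3 <- function(genes, terminators = NULL, path, chrom = "chr") {
  gr_genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr_genes)$type <- "gene"
  S4Vectors::mcols(gr_genes)$locus_tag <- genes$locus_tag
  S4Vectors::mcols(gr_genes)$operon_id <- genes$operon_id
  S4Vectors::mcols(gr_genes)$expression_cpm <- genes$expression_cpm
  S4Vectors::mcols(gr_genes)$essentiality_rank <- genes$essentiality_rank
  gr <- gr_genes
  if (!is.null(terminators) && nrow(terminators) > 0) {
    gr_term <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = terminators$position,
                                end = terminators$position),
      strand = terminators$strand)
    S4Vectors::mcols(gr_term)$type <- "terminator"
    gr <- suppressWarnings(c(gr_genes, gr_term))
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
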
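#' Shortest distance between two positions on a circular genome
#'
#' `min(|a - b|, L - |a - b|)` for 1-based positions on a circle of length
#' `L`; symmetric and never larger than `L / 2`.
#'
#' @param a,b 1-based positions (vectorised).
#' @param genome_length Genome length in bp.
#' @return Integer distances in bp.
#' @export
circular_distance <- function(a, b, genome_length) {
  stopifnot(genome_length > 0)
  if (any(a < 1 | a > genome_length) || any(b < 1 | b > genome_length))
    stop("positions must lie in [1, genome_length]")
  dd <- abs(a - b)
  as.integer(pmin(dd, genome_length - dd))
}

# clockwise walk length from a to b (0 when a == b)
.cw_dist <- function(a, b, genome_length) (b - a) %% genome_length

# is x strictly between a and b walking clockwise from a to b?
.circ_between <- function(x, a, b, genome_length) {
  da <- .cw_dist(a, x, genome_length)
  db <- .cw_dist(a, b, genome_length)
  da > 0 & da < db
}

#' Nearest replication origin to a site
#'
#' Minimises [circular_distance()] over the supplied origins; ties are broken
#' by origin name order (as listed).
#'
#' @param position 1-based site position.
#' @param origins Tibble with columns `name`, `position`.
#' @param genome_length Genome length in bp.
#' @return List with `name` and `distance` (bp).
#' @export
nearest_origin <- function(position, origins, genome_length) {
  stopifnot(nrow(origins) >= 1,
            all(c("name", "position") %in% names(origins)))
  d <- circular_distance(position, origins$position, genome_length)
  i <- which.min(d)  # first minimum = first by listed name order
  list(name = origins$name[i], distance = d[i])
}

#' Assign a chromatin compartment label to a position
#'
#' Returns the label of the interval covering the position; positions falling
#' in an annotation gap take the label of the nearest interval boundary
#' (circular distance).
#'
#' @param position 1-based position.
#' @param intervals Tibble with 1-based inclusive `start`, `end` and `label`
#'   (`"A"` or `"B"`), non-overlapping.
#' @param genome_length Genome length in bp (used for gap resolution on the
#'   circle).
#' @return Compartment label (character scalar).
#' @export
assign_compartment <- function(position, intervals, genome_length) {
  if (nrow(intervals) == 0) stop("empty compartment interval set")
  hit <- which(intervals$start <= position & position <= intervals$end)
  if (length(hit)) return(intervals$label[hit[1]])
  bound_dist <- pmin(circular_distance(position, intervals$start, genome_length),
                     circular_distance(position, intervals$end, genome_length))
  intervals$label[which.min(bound_dist)]
}

#' Classify the transcriptional context of an integration site
#'
#' Decides whether a cassette integrated at `position` is insulated from
#' read-through transcription, and if not, which flanking gene is the likely
#' read-through donor. The rules operate on the immediate flanking genes on
#' the circular genome:
#'
#' * site inside a gene: never insulated, the overlapped gene is the donor;
#' * left flank on `-` and right flank on `+` (divergent promoters facing the
#'   site): insulated, no donor;
#' * a flanking gene transcribing toward the site (left `+`, or right `-`)
#'   with no same-strand terminator between its 3' end and the site donates
#'   read-through; co-operonic flanks always read through;
#' * convergent 3'/3' flanks with no intervening terminator are unresolvable:
#'   not insulated, the nearer upstream gene is reported as donor and the
#'   `ambiguous` flag is set.
#'
#' @param position 1-based site position.
#' @param genes Tibble with `locus_tag`, `start`, `end`, `strand`,
#'   `expression_cpm`, `operon_id` (NA when monocistronic).
#' @param terminators Tibble with `position`, `strand` (may be empty).
#' @param genome_length Genome length in bp.
#' @return List with `insulated`, `donor` (locus tag or `NA`),
#'   `donor_expression_cpm`, `ambiguous`.
#' @export
classify_site_context <- function(position, genes, terminators, genome_length) {
  if (nrow(genes) == 0) stop("no genes supplied; cannot classify site context")
  stopifnot(all(genes$start <= genes$end))

  donor_out <- function(insulated, donor_tag, ambiguous) {
    cpm <- if (is.na(donor_tag)) NA_real_ else
      genes$expression_cpm[match(donor_tag, genes$locus_tag)]
    list(insulated = insulated, donor = donor_tag,
         donor_expression_cpm = cpm, ambiguous = ambiguous)
  }

  inside <- which(genes$start <= position & position <= genes$end)
  if (length(inside))
    return(donor_out(FALSE, genes$locus_tag[inside[1]], FALSE))

  # flanking genes on the circle
  left_cand <- which(genes$end < position)
  left_i <- if (length(left_cand)) left_cand[which.max(genes$end[left_cand])]
            else which.max(genes$end)  # wrap
  right_cand <- which(genes$start > position)
  right_i <- if (length(right_cand)) right_cand[which.min(genes$start[right_cand])]
             else which.min(genes$start)  # wrap
  L <- genes[left_i, ]; R <- genes[right_i, ]

  term_blocks <- function(from, to, strand) {
    if (nrow(terminators) == 0) return(FALSE)
    same <- terminators[terminators$strand == strand, , drop = FALSE]
    if (nrow(same) == 0) return(FALSE)
    any(.circ_between(same$position, from, to, genome_length))
  }

  co_operonic <- !is.na(L$operon_id) && !is.na(R$operon_id) &&
    identical(L$operon_id, R$operon_id)

  left_donates <- L$strand == "+" &&
    (co_operonic || !term_blocks(L$end, position, "+"))
  right_donates <- R$strand == "-" &&
    (co_operonic || !term_blocks(position, R$start, "-"))

  if (!left_donates && !right_donates) {
    divergent <- L$strand == "-" && R$strand == "+"
    return(donor_out(divergent, NA_character_, FALSE))
  }
  if (left_donates && right_donates) {
    # convergent 3'/3' with no terminator: flag, report the nearer gene
    d_left <- .cw_dist(L$end, position, genome_length)
    d_right <- .cw_dist(position, R$start, genome_length)
    nearer <- if (d_left <= d_right) L$locus_tag else R$locus_tag
    return(donor_out(FALSE, nearer, TRUE))
  }
  donor_out(FALSE, if (left_donates) L$locus_tag else R$locus_tag, FALSE)
}

#' Build the per-site genome-context table
#'
#' Annotates every target site with its nearest replication origin and
#' circular distance, chromatin compartment, insulation call and read-through
#' donor.
#'
#' @param sites Tibble with `name`, `position` (1-based), optional
#'   `cassette_strand`.
#' @param genes Gene tibble (see [classify_site_context()]).
#' @param origins Origin tibble (see [nearest_origin()]).
#' @param intervals Compartment tibble (see [assign_compartment()]).
#' @param terminators Terminator tibble (may be empty).
#' @param genome_length Genome length in bp.
#' @return Tibble with one row per site: `site`, `position`, `nearest_ori`,
#'   `ori_distance`, `compartment`, `insulated`, `readthrough_donor`,
#'   `donor_expression_cpm`, `ambiguous`.
#' @export
build_site_table <- function(sites, genes, origins, intervals, terminators,
                             genome_length) {
  if (nrow(sites) == 0)
    return(tibble::tibble(site = character(), position = integer(),
                          nearest_ori = character(), ori_distance = integer(),
                          compartment = character(), insulated = logical(),
                          readthrough_donor = character(),
                          donor_expression_cpm = double(),
                          ambiguous = logical()))
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    pos <- sites$position[i]
    ori <- nearest_origin(pos, origins, genome_length)
    ctx <- classify_site_context(pos, genes, terminators, genome_length)
    tibble::tibble(site = sites$name[i], position = as.integer(pos),
                   nearest_ori = ori$name, ori_distance = ori$distance,
                   compartment = assign_compartment(pos, intervals, genome_length),
                   insulated = ctx$insulated,
                   readthrough_donor = ctx$donor,
                   donor_expression_cpm = ctx$donor_expression_cpm,
                   ambiguous = ctx$ambiguous)
  })
  dplyr::bind_rows(rows)
}

#' Pop-in integrant fraction
#'
#' Percentage of blue (reporter-positive) colony-forming units among all
#' screened CFUs after the integration step.
#'
#' @param blue_cfu,total_cfu Non-negative counts with
#'   `0 <= blue_cfu <= total_cfu` and `total_cfu > 0` (vectorised).
#' @return Percentage in `[0, 100]`.
#' @export
popin_fraction <- function(blue_cfu, total_cfu) {
  if (any(total_cfu <= 0)) stop("`total_cfu` must be positive")
  if (any(blue_cfu < 0 | blue_cfu > total_cfu))
    stop("`blue_cfu` must lie in [0, total_cfu]")
  100 * blue_cfu / total_cfu
}

#' Mean pop-in fraction per chromatin compartment
#'
#' Arithmetic mean of per-site pop-in percentages within each compartment
#' label; labels with no sites are omitted with a warning.
#'
#' @param fractions Tibble with `site` and `fraction` (percent).
#' @param contexts Site-context table from [build_site_table()].
#' @return Tibble with `compartment` and `mean_fraction`.
#' @export
compartment_mean_fraction <- function(fractions, contexts) {
  joined <- dplyr::inner_join(fractions, contexts, by = "site")
  if (nrow(joined) < nrow(fractions))
    stop("every site with a fraction must have a compartment assignment")
  out <- joined |>
    dplyr::group_by(compartment = .data$compartment) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop")
  missing <- setdiff(unique(contexts$compartment), out$compartment)
  if (length(missing))
    warning(sprintf("no screened sites in compartment(s): %s",
                    paste(missing, collapse = ", ")))
  out
}
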
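# Occurrence preparation: record-count filter with taxonomic coverage
# accounting, spatial thinning to the model grid, and pseudo-absence
# (background) sampling.

#' Filter species by minimum record count
#'
#' Keeps species with strictly more than `min_records` occurrence records
#' ("more than 25" by default) and reports checklist coverage: how many
#' species, families, and genera of the full input checklist are retained.
#' Percentages are rounded half-up to one decimal.
#'
#' @param occurrence_sets list of [occurrence_set()] objects (the checklist).
#' @param min_records strict lower bound on record count; default 25.
#' @return list with `retained` (the passing occurrence sets) and `report`,
#'   a `coverage_report` with totals, covered counts, and percentages.
#' @export
filter_min_occurrences <- function(occurrence_sets, min_records = 25) {
  if (min_records < 0) fc_stop("fc_invalid_parameter", "min_records must be >= 0")
  counts <- vapply(occurrence_sets, function(s) nrow(s$records), 0L)
  keep <- counts > min_records
  tax <- function(sets, field) {
    v <- vapply(sets, function(s) as.character(s$taxonomy[[field]]), "")
    unique(v[!is.na(v) & nzchar(v)])
  }
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  fam_all <- tax(occurrence_sets, "family"); fam_kept <- tax(occurrence_sets[keep], "family")
  gen_all <- tax(occurrence_sets, "genus");  gen_kept <- tax(occurrence_sets[keep], "genus")
  report <- structure(list(
    n_species_total = length(occurrence_sets),
    n_species_retained = sum(keep),
    pct_retained = pct(sum(keep), length(occurrence_sets)),
    n_families_total = length(fam_all),
    n_families_covered = length(fam_kept),
    pct_families = pct(length(fam_kept), length(fam_all)),
    n_genera_total = length(gen_all),
    n_genera_covered = length(gen_kept),
    pct_genera = pct(length(gen_kept), length(gen_all)),
    min_records = min_records), class = "coverage_report")
  list(retained = occurrence_sets[keep], report = report)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage: %d/%d species retained (%.1f%%); families %d/%d (%.1f%%); genera %d/%d (%.1f%%)\n",
    x$n_species_retained, x$n_species_total, x$pct_retained,
    x$n_families_covered, x$n_families_total, x$pct_families,
    x$n_genera_covered, x$n_genera_total, x$pct_genera))
  invisible(x)
}

#' Thin occurrence records to the model grid
#'
#' Deduplicates records to at most one presence per grid cell; records
#' falling outside the grid extent are dropped (their count is reported in
#' the `n_dropped` attribute).
#'
#' @param occ an [occurrence_set()].
#' @param grid a [climate_grid()].
#' @return integer vector of unique presence cell indices (sorted), with
#'   attribute `n_dropped`.
#' @export
thin_to_grid <- function(occ, grid) {
  idx <- cell_index(grid, occ$records$lon, occ$records$lat)
  dropped <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    fc_stop("fc_no_usable_records",
            "species %s: no records inside the grid extent", occ$species_id)
  structure(sort(unique(idx)), n_dropped = dropped)
}

#' Sample background (pseudo-absence) cells
#'
#' Uniform sample without replacement from the grid cells that are not
#' presence cells. If fewer cells are available than requested, the sample
#' is clamped to what is available with a warning.
#'
#' @param grid a [climate_grid()].
#' @param presence_cells integer cell indices to exclude.
#' @param n_background requested sample size (>= 1).
#' @param seed integer seed; fixed seed gives an identical cell set.
#' @return sorted integer vector of background cell indices.
#' @export
sample_background <- function(grid, presence_cells, n_background, seed = 1) {
  if (n_background < 1) fc_stop("fc_invalid_parameter", "n_background must be >= 1")
  avail <- setdiff(seq_len(n_cells(grid)), presence_cells)
  if (!length(avail)) fc_stop("fc_no_background", "no non-presence cells available")
  if (n_background > length(avail)) {
    fc_warn("fc_background_clamped",
            "requested %d background cells, only %d available",
            n_background, length(avail))
    n_background <- length(avail)
  }
  fc_with_seed(seed, sort(avail[sample.int(length(avail), n_background)]))
}

#' Build the per-species modelling dataset
#'
#' Thins presences to the grid, samples background cells (default ten times
#' the presence count, capped at 10000), and extracts the covariate rows for
#' both. Presence and background cells are disjoint by construction.
#'
#' @param occ an [occurrence_set()].
#' @param grid the current-period [climate_grid()].
#' @param n_background background size; default `min(10 * n_presence, 10000)`.
#' @param seed integer seed for background sampling.
#' @return object of class `modeling_dataset`: species_id, presence_cells,
#'   background_cells, covariate matrices `X_presence` / `X_background`, and
#'   the covariate names.
#' @export
build_modeling_dataset <- function(occ, grid, n_background = NULL, seed = 1) {
  pres <- thin_to_grid(occ, grid)
  if (is.null(n_background)) n_background <- min(10L * length(pres), 10000L)
  bg <- sample_background(grid, pres, n_background, seed)
  X <- covariate_matrix(grid)
  structure(list(species_id = occ$species_id,
                 presence_cells = as.integer(pres),
                 background_cells = as.integer(bg),
                 X_presence = X[pres, , drop = FALSE],
                 X_background = X[bg, , drop = FALSE],
                 covariate_names = colnames(X)),
            class = "modeling_dataset")
}
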
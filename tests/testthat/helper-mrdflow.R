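# Construct a small non-negative blank set with exact sample mean m and
# sample SD s (n - 1 denominator), so printed (LOD, LLOQ) pairs can be mapped
# to an explicit blank set. Two symmetric points suffice while s <= m*sqrt(2);
# beyond that (blank sets dominated by zeros have SD ~ twice the mean) three
# zeros are padded in: {0, 0, 0, 2.5m - u, 2.5m + u} with u^2 = 2s^2 - 3.75m^2.
blanks_with_moments <- function(m, s) {
  if (s <= m * sqrt(2)) {
    return(c(m - s / sqrt(2), m + s / sqrt(2)))
  }
  u <- sqrt(2 * s^2 - 3.75 * m^2)
  stopifnot(u <= 2.5 * m)
  c(0, 0, 0, 2.5 * m - u, 2.5 * m + u)
}

# Invert the two linear detection-limit formulas for the blank moments:
# lod = m + 3 s, lloq = m + 10 s.
solve_blank_moments <- function(lod, lloq) {
  s <- (lloq - lod) / 7
  list(m = lod - 3 * s, s = s)
}

# Minimal hand-built specimen table: equal tubes, chosen event counts.
specimen_table <- function(mm_events, mast_events = 0, analytical_input = 1e7,
                           stained_cells = 20e6, viability = 0.9,
                           timepoint = "post_asct_1y", route = "bedside_iliac") {
  n <- max(
    length(mm_events), length(mast_events), length(analytical_input),
    length(stained_cells), length(timepoint)
  )
  tibble::tibble(
    specimen_id = sprintf("S%05d", seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    timepoint = factor(rep_len(timepoint, n), levels = mrd_timepoints),
    collection_route = factor(rep_len(route, n), levels = mrd_routes),
    aspirate_volume_ml = 5,
    cellularity_per_ml = 11.5e6,
    viability = rep_len(viability, n),
    stained_cells = rep_len(stained_cells, n),
    acquired_events_tube_a = rep_len(analytical_input, n) / 2,
    acquired_events_tube_b = rep_len(analytical_input, n) / 2,
    mm_pc_events = rep_len(mm_events, n),
    n_pc_events = 0,
    mast_cell_events = rep_len(mast_events, n),
    daratumumab_exposed = FALSE
  )
}
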
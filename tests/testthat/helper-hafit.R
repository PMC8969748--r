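# shared fixtures, built in code

STD_FREQS <- c(0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
PTA_FREQS <- c(0.5, 0.75, 1, 1.5, 2, 3, 4)
HA_EDGES <- c(0.1, 0.7, 1.4, 2.8, 5.6, 8)

flat_audiogram <- function(thr, freqs = STD_FREQS, label = "flat") {
  audiogram(freqs, rep(thr, length(freqs)), label)
}

test_ha_config <- function(...) {
  ha_config(ig65_db = rep(20, 5), ig85_db = rep(10, 5), ct_db_spl = rep(45, 5),
            ...)
}

# geometric band centers of the 5 HA channels (Hz)
band_centers_hz <- function(edges = HA_EDGES) {
  sqrt(edges[-1] * edges[-length(edges)]) * 1000
}

# steady-state level metered over a window that skips onset/offset transients
steady_level <- function(wf, skip_s = 0.2) {
  dur <- length(wf$samples) / wf$sample_rate_hz
  wf_level_db_spl(wf, skip_s, dur - 0.02)
}

# cross-test cache for the acceptance suite (criterion 2 feeds criterion 3)
.acceptance_cache <- new.env(parent = emptyenv())
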
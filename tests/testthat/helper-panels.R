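# hand-built panels for gating tests ----------------------------------------

# one tube from explicit channel vectors; scatter defaults pass the gates
manual_tube <- function(hx103, egfr_ab = rep(0, length(hx103)),
                        cd45 = rep(0, length(hx103)),
                        fsc = rep(5e4, length(hx103)),
                        ssc = rep(3e4, length(hx103))) {
  data.frame(event_id = seq_along(hx103), fsc = fsc, ssc = ssc,
             cd45 = cd45, egfr_ab = egfr_ab, hx103 = hx103)
}

manual_panel <- function(dmso, isotype = dmso, stained = dmso,
                         blocked = stained, specimen_id = "manual") {
  structure(list(specimen_id = specimen_id, tissue_type = "surgical",
                 seed = NA_integer_, n_events = nrow(dmso),
                 populations = NULL,
                 tubes = list(dmso_control = dmso,
                              isotype_control = isotype,
                              stained = stained,
                              gefitinib_blocked = blocked)),
            class = "sample_panel")
}

# brute-force Youden search used as the independent oracle
brute_force_youden <- function(values, labels) {
  v <- sort(unique(values))
  cands <- (head(v, -1) + tail(v, -1)) / 2
  pos <- values[labels]
  neg <- values[!labels]
  j <- vapply(cands, function(ct) mean(pos >= ct) + mean(neg < ct) - 1,
              numeric(1))
  list(cands = cands, j = j, jmax = max(j))
}
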
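# Lazily computed fixtures shared across test files (notably the full
# phantom pipeline, which is expensive and consumed by several acceptance
# blocks). Everything is deterministic: fixed spec, fixed seed.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fixture_phantom <- function() {
  cached("phantom", generate_capsule(scaled_phantom_spec(), seed = 101L))
}

fixture_pipeline <- function() {
  cached("pipeline", {
    ph <- fixture_phantom()
    pp <- preprocess_params()
    m <- clean_binary(binarize(smooth_edge_preserving(ph$volume, 1), pp), pp)
    phases <- split_capsule_phases(m)
    labels <- segment_pellets(phases$pellets)
    list(mask = m, phases = phases, labels = labels)
  })
}

fixture_records <- function() {
  cached("records", extract_pellets(fixture_pipeline()$labels))
}

fixture_features <- function() {
  cached("features", {
    tab <- feature_table(fixture_records())
    ph <- fixture_phantom()
    seg <- fixture_pipeline()$labels
    tru <- ph$labels$data
    sel <- seg$data > 0L & tru > 0L
    ov <- table(true = tru[sel], seg = seg$data[sel])
    seg2true <- integer(max(seg$data))
    for (j in seq_len(ncol(ov)))
      seg2true[as.integer(colnames(ov)[j])] <-
        as.integer(rownames(ov)[which.max(ov[, j])])
    truth_row <- match(seg2true[tab$label], ph$truth$id)
    list(table = tab,
         truth_broken = ph$truth$broken[truth_row],
         truth_diameter_um = ph$truth$diameter_um[truth_row],
         truth_solid_voxels = ph$truth$solid_voxels[truth_row])
  })
}
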
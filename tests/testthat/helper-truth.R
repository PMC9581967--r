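# Ground-truth segment pose for a RIGID filament instance: the canonical
# reference pose whose projection matches the segment window, derived purely
# from the generator's placement parameters (independent of the alignment
# path under test).
truth_segment_pose <- function(seg, fil, lattice, micrograph_shape, apix) {
  cen <- micrograph_shape / 2 + 1
  c_phys <- (seg$centre_px - cen) * apix
  dirv <- c(cos(fil$direction_deg * pi / 180), sin(fil$direction_deg * pi / 180))
  p0 <- fil$backbone[1, 1:2] # axis point at lattice z = 0
  z <- sum((c_phys - p0) * dirv)
  kc <- round(z / lattice$rise)
  q0 <- p0 + dirv * (kc * lattice$rise)
  pose(fil$roll_deg + kc * lattice$twist, 90, fil$direction_deg,
       q0[1] - c_phys[1], q0[2] - c_phys[2])
}

# Extract segments from a simulated dataset, keeping the matching filament
# instance alongside each segment.
segments_with_truth <- function(ds, box, apix) {
  segs <- list()
  fils <- list()
  for (m in seq_along(ds$micrographs)) {
    sim <- ds$micrographs[[m]]
    for (tr in trace_filaments(sim$micrograph, truth = sim$truth)) {
      ss <- extract_segments(sim$micrograph, tr, box = box, ctf = sim$ctf)
      idx <- as.integer(sub(".*_f", "", tr$filament_id))
      for (s in ss) {
        segs <- c(segs, list(s))
        fils <- c(fils, list(ds$instances[[m]][[idx]]))
      }
    }
  }
  list(segments = segs, fils = fils)
}
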
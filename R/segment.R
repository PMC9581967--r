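#' Trace filaments in a micrograph
#'
#' Ground-truth passthrough (when `truth` is supplied, for pipeline
#' isolation) or a simple matched-filter ridge tracer: Gaussian smoothing at
#' the filament scale, thresholding, connected components, and per-component
#' axial binning into an ordered polyline. The neural-network pickers used
#' in practice are deliberately out of scope.
#'
#' @param micrograph an [image2d()].
#' @param truth optional truth table list (from [simulate_micrograph()]);
#'   its `filaments` polylines are returned directly.
#' @param template_width filament width used for the smoothing scale
#'   (Angstrom).
#' @param threshold_sigmas detection threshold in sds of the smoothed image.
#' @param min_length_a minimum accepted trace arc length (Angstrom).
#' @param polarity `"auto"`, `"dark"` (CTF-modulated stain-like contrast) or
#'   `"bright"`.
#' @return list of `filament_trace` objects: `list(micrograph_id, polyline
#'   (n x 2, px, 1-based), estimated_width (px))`.
#' @export
trace_filaments <- function(micrograph, truth = NULL, template_width = 220,
                            threshold_sigmas = 5, min_length_a = 300,
                            polarity = c("auto", "dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(micrograph, "image2d"))
  if (!all(is.finite(micrograph$values))) stop("trace_filaments: non-finite micrograph")
  n <- box_size(micrograph)
  apix <- micrograph$apix
  cen <- n / 2 + 1
  if (!is.null(truth)) {
    fil <- truth$filaments
    if (is.null(fil) || nrow(fil) == 0L) return(list())
    return(lapply(split(fil, fil$filament_id), function(df) {
      df <- df[order(df$point_index), ]
      structure(list(micrograph_id = df$micrograph_id[1],
                     filament_id = df$filament_id[1],
                     polyline = cbind(df$x / apix + cen, df$y / apix + cen),
                     estimated_width = template_width / apix),
                class = "filament_trace")
    }))
  }
  sg_px <- template_width / apix / 2
  k <- freq_index(n) / n
  gauss_ft <- exp(-2 * pi^2 * sg_px^2 * outer(k^2, k^2, `+`))
  sm <- Re(ifft_centered(fft_centered(micrograph$values) * gauss_ft))
  if (polarity == "auto")
    polarity <- if (abs(min(sm - mean(sm))) > abs(max(sm - mean(sm)))) "dark" else "bright"
  if (polarity == "dark") sm <- -sm
  # robust threshold: the filament itself inflates a plain sd
  thr <- stats::median(sm) + threshold_sigmas * stats::mad(sm)
  bin <- sm > thr
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labs <- as.vector(EBImage::imageData(lab))
  coords <- which(labs > 0)
  comp <- split(coords, labs[coords])
  out <- list()
  for (cc in comp) {
    xy <- cbind((cc - 1L) %% n + 1L, (cc - 1L) %/% n + 1L)
    if (nrow(xy) < 20L) next
    wv <- sm[cc] - thr # intensity-weighted centroids: sub-pixel, low jitter
    ctr <- colMeans(xy)
    pc <- eigen(stats::cov(xy), symmetric = TRUE)
    ax1 <- pc$vectors[, 1]
    t_par <- (xy[, 1] - ctr[1]) * ax1[1] + (xy[, 2] - ctr[2]) * ax1[2]
    bw <- max(4, sg_px / 2) # axial bin width (px)
    bins <- round(t_par / bw)
    pts <- t(vapply(split(seq_len(nrow(xy)), bins), function(ix) {
      colSums(xy[ix, , drop = FALSE] * wv[ix]) / sum(wv[ix])
    }, numeric(2)))
    pts <- pts[order(as.numeric(rownames(pts))), , drop = FALSE]
    if (nrow(pts) >= 4L) pts <- pts[-c(1L, nrow(pts)), , drop = FALSE] # ends half-filled
    if (nrow(pts) >= 5L) { # smooth the centroid polyline
      sm3 <- function(z) stats::filter(z, rep(1 / 3, 3), sides = 2)
      inner <- 2:(nrow(pts) - 1L)
      pts[inner, 1] <- sm3(pts[, 1])[inner]
      pts[inner, 2] <- sm3(pts[, 2])[inner]
    }
    if (nrow(pts) < 2L) next
    arc <- sum(sqrt(rowSums(diff(pts)^2))) * apix
    if (arc < min_length_a) next
    t_perp <- -(xy[, 1] - ctr[1]) * ax1[2] + (xy[, 2] - ctr[2]) * ax1[1]
    out[[length(out) + 1L]] <-
      structure(list(micrograph_id = NA_character_,
                     filament_id = sprintf("trace%02d", length(out) + 1L),
                     polyline = pts,
                     estimated_width = 2 * stats::sd(t_perp)),
                class = "filament_trace")
  }
  out
}

#' Arc length of a filament trace
#' @param trace a `filament_trace`.
#' @param apix pixel size (Angstrom), to return Angstrom.
#' @export
trace_arc_length <- function(trace, apix = 1) {
  sum(sqrt(rowSums(diff(trace$polyline)^2))) * apix
}

# Interpolate a polyline at arc position s (px units); returns point and
# unit tangent.
polyline_at <- function(poly, s_px) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  s_px <- max(0, min(s_px, cum[length(cum)]))
  i <- findInterval(s_px, cum, rightmost.closed = TRUE)
  i <- max(1L, min(i, length(seg)))
  f <- (s_px - cum[i]) / seg[i]
  p <- poly[i, ] + f * (poly[i + 1L, ] - poly[i, ])
  tg <- (poly[i + 1L, ] - poly[i, ]) / seg[i]
  list(point = p, tangent = tg)
}

#' Extract overlapping normalized segments along a trace
#'
#' Boxes of `box` pixels centred on the polyline every `step` Angstrom,
#' starting half a box in so each window fits. Each segment image is
#' background-normalized (mean 0, sd 1) in the region outside the filament:
#' pixels whose perpendicular distance to the local axis exceeds
#' `filament_radius` (falling back to the corner annulus if that region is
#' nearly empty). The in-plane filament direction is stored as `psi_prior`.
#'
#' @param micrograph an [image2d()].
#' @param trace a `filament_trace`.
#' @param box box edge (px, even).
#' @param step inter-box distance (Angstrom, > 0).
#' @param filament_radius filament outer radius (Angstrom) for the
#'   background region.
#' @param ctf a [ctf_params()] or `NULL`, attached to every segment.
#' @return list of `segment_particle` objects: `list(image, micrograph_id,
#'   filament_id, arc_position (A), psi_prior (deg), pose (NULL), ctf,
#'   status = "active")`. A trace shorter than one box gives `list()`.
#' @export
extract_segments <- function(micrograph, trace, box = 64, step = NULL,
                             filament_radius = 115, ctf = NULL) {
  stopifnot(inherits(micrograph, "image2d"), inherits(trace, "filament_trace"))
  if (box %% 2L != 0L) stop("extract_segments: box must be even")
  apix <- micrograph$apix
  if (is.null(step)) step <- box * apix / 4 # default inter-box distance
  if (step <= 0) stop("extract_segments: step must be > 0")
  L <- trace_arc_length(trace, apix)
  box_a <- box * apix
  if (L < box_a) return(list())
  n_seg <- floor((L - box_a) / step) + 1L
  n <- box_size(micrograph)
  segs <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    s_a <- box_a / 2 + (i - 1L) * step
    loc <- polyline_at(trace$polyline, s_a / apix)
    c_px <- round(loc$point)
    ix <- c_px[1] - box %/% 2L + seq_len(box) - 1L
    iy <- c_px[2] - box %/% 2L + seq_len(box) - 1L
    if (ix[1] < 1L || iy[1] < 1L || ix[box] > n || iy[box] > n) next
    win <- micrograph$values[ix, iy]
    psi <- atan2(loc$tangent[2], loc$tangent[1]) * 180 / pi
    win <- normalize_background(win, apix, psi, filament_radius)
    segs[[i]] <- structure(
      list(image = image2d(win, apix),
           micrograph_id = trace$micrograph_id,
           filament_id = if (!is.null(trace$filament_id)) trace$filament_id else NA,
           arc_position = s_a,
           centre_px = c_px,
           psi_prior = psi,
           pose = NULL, ctf = ctf, status = "active"),
      class = "segment_particle")
  }
  segs[!vapply(segs, is.null, logical(1))]
}

# Normalize to mean 0 / sd 1 in the background region of a segment window.
normalize_background <- function(win, apix, psi_deg, filament_radius) {
  b <- nrow(win)
  x <- (seq_len(b) - (b / 2 + 1)) * apix
  gx <- matrix(x, b, b)
  gy <- t(gx)
  a <- deg2rad(psi_deg)
  perp <- abs(-sin(a) * gx + cos(a) * gy)
  bg <- perp > filament_radius
  if (mean(bg) < 0.05) {
    r <- sqrt(gx^2 + gy^2)
    bg <- r > 0.48 * b * apix
  }
  mu <- mean(win[bg])
  sdv <- stats::sd(win[bg])
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  (win - mu) / sdv
}

# --- projection matching ----------------------------------------------------

# Cross-correlation map of (Fourier, natural-order) reference REF against
# image transform IMG; entry for shift s lives at index (s mod n) + 1 and
# equals <shift(ref, s), img>.
cc_map <- function(REF, IMG) Re(stats::fft(Conj(REF) * IMG, inverse = TRUE)) /
  length(REF)

# Best shift within a window (px) of a natural-order cc map; parabolic
# sub-pixel fit.
cc_peak <- function(cc, max_shift_px) {
  n <- nrow(cc)
  w <- min(floor(max_shift_px), n %/% 2 - 1L)
  ii <- ((-w:w) %% n) + 1L
  sub <- cc[ii, ii, drop = FALSE]
  k <- which.max(sub)
  i <- (k - 1L) %% nrow(sub) + 1L
  j <- (k - 1L) %/% nrow(sub) + 1L
  dx <- dy <- 0
  if (i > 1 && i < nrow(sub)) {
    d <- (sub[i - 1, j] - sub[i + 1, j]) / 2 /
      (sub[i - 1, j] - 2 * sub[i, j] + sub[i + 1, j])
    if (is.finite(d) && abs(d) < 1) dx <- d
  }
  if (j > 1 && j < ncol(sub)) {
    d <- (sub[i, j - 1] - sub[i, j + 1]) / 2 /
      (sub[i, j - 1] - 2 * sub[i, j] + sub[i, j + 1])
    if (is.finite(d) && abs(d) < 1) dy <- d
  }
  list(score = sub[i, j],
       shift = c(i - (w + 1L) + dx, j - (w + 1L) + dy))
}

# Evaluate candidates (data.frame rot/tilt/psi) for one image; returns best
# pose row with shift (A) and NCC score. Ties keep the first (lowest-index)
# candidate. IMG: natural-order FFT of the (centred) image, i.e.
# fft(ifftshift(values)) with DC zeroed; img_norm: sqrt(sum |IMG|^2 / n^2).
match_candidates <- function(IMG, img_norm, prj, ctf, cand, max_shift_px) {
  n <- nrow(IMG)
  apix <- prj$apix
  best <- NULL
  cvals <- if (is.null(ctf)) 1 else {
    kx <- matrix(freq_index_natural(n) / (n * apix), n, n)
    ctf_evaluate(ctf, kx, t(kx))
  }
  flip <- c(1L, seq.int(n, 2L)) # index of -k in natural order
  for (ci in seq_len(nrow(cand))) {
    S <- project_slice_ft_bare(prj, cand$rot[ci], cand$tilt[ci], cand$psi[ci])
    S <- (S + Conj(S[flip, flip])) / 2 # the reference projection is real
    S <- S * cvals
    S[1, 1] <- 0 # zero-mean reference
    rnorm_ <- sqrt(sum(Mod(S)^2) / n^2)
    if (rnorm_ == 0) next
    pk <- cc_peak(cc_map(S, IMG), max_shift_px)
    score <- pk$score / (rnorm_ * img_norm)
    if (is.null(best) || score > best$score) {
      best <- list(score = score,
                   pose = pose(cand$rot[ci], cand$tilt[ci], cand$psi[ci],
                               pk$shift[1] * apix, pk$shift[2] * apix))
    }
  }
  best
}

# Natural-order FFT of a centred image, DC zeroed (matching convention).
image_match_ft <- function(values) {
  IMG <- stats::fft(ifftshift(values))
  IMG[1, 1] <- 0
  IMG
}

# Multi-stage local pose refinement around a starting pose.
refine_pose_local <- function(IMG, img_norm, prj, ctf, start, stages,
                              max_shift_px, tilt_limits = c(0, 180)) {
  cur <- start
  best <- NULL
  for (st in stages) {
    gr <- expand.grid(rot = cur$rot + seq(-st$range, st$range, st$step),
                      tilt = cur$tilt + seq(-st$range, st$range, st$step),
                      psi = cur$psi + seq(-st$range, st$range, st$step))
    gr <- gr[gr$tilt >= tilt_limits[1] & gr$tilt <= tilt_limits[2], , drop = FALSE]
    res <- match_candidates(IMG, img_norm, prj, ctf, gr, max_shift_px)
    if (!is.null(res)) {
      cur <- res$pose
      best <- res
    }
  }
  best
}

#' Align segments to a reference by projection matching
#'
#' Exhaustive normalized cross-correlation over a prior-restricted pose grid
#' (full 360 degrees in `rot`; `tilt` within `tilt_width` of 90 degrees —
#' filaments lie in the plane of the ice; `psi` within `psi_width` of the
#' trace tangent), followed by local angle/shift polish. Ties are broken by
#' the lowest grid index. No helical symmetry is imposed.
#'
#' @param segments list of `segment_particle`s.
#' @param reference a [density_map()] (or a [projector()] of one); must not
#'   be all zero. A soft spherical mask is applied before matching.
#' @param angular_step coarse grid step (degrees).
#' @param tilt_width,psi_width prior half-widths (degrees).
#' @param shift_range maximum shift searched (Angstrom).
#' @param polish_step final local step (degrees); `NULL` disables polish.
#' @param method `"coarse_fine"` (grid + polish) or `"exhaustive"` (single
#'   full grid at `polish_step` over the same prior windows, for validation).
#' @param mask whether to soft-mask the reference.
#' @param bin Fourier-crop binning factor for the coarse search (`NULL` =
#'   bin to a 32 px working box).
#' @param full_polish run the final polish stage at full sampling (default);
#'   `FALSE` keeps the whole search binned, appropriate when the consensus
#'   is resolution-limited anyway.
#' @return list with `poses` (data.frame, one row per segment) and `scores`
#'   (NCC values).
#' @export
align_segments <- function(segments, reference, angular_step = 10,
                           tilt_width = 15, psi_width = 15,
                           shift_range = 40, polish_step = 1,
                           method = c("coarse_fine", "exhaustive"),
                           mask = TRUE, bin = NULL, full_polish = TRUE) {
  method <- match.arg(method)
  if (!length(segments)) stop("align_segments: no segments")
  if (inherits(reference, "projector")) {
    prj <- reference
    reference <- NULL
  } else {
    if (all(reference$values == 0)) stop("align_segments: reference is all zero")
    if (mask) {
      n <- box_size(reference)
      msk <- soft_mask(n, reference$apix, radius = (n / 2 - 1) * reference$apix,
                       soft_edge = 4 * reference$apix)
      reference <- density_map(reference$values * msk$values, reference$apix)
    }
    prj <- projector(reference)
  }
  apix <- prj$apix
  n <- prj$n
  # binned projector for the coarse search (cache-friendly); full-size polish
  if (is.null(bin)) bin <- max(1L, n %/% 32L)
  bin <- as.integer(bin)
  if (bin > 1L && (!is.null(reference)) && (n %/% bin) %% 2L == 0L &&
      method == "coarse_fine") {
    prjB <- projector(bin_fourier(reference, bin))
  } else {
    bin <- 1L
    prjB <- prj
  }
  nb <- n %/% bin
  max_shift_px <- max(1, shift_range / apix)
  rows <- vector("list", length(segments))
  scores <- numeric(length(segments))
  crop <- c(seq_len(nb %/% 2), n - nb %/% 2 + seq_len(nb %/% 2)) # low freqs
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    IMG <- image_match_ft(sg$image$values)
    img_norm <- sqrt(sum(Mod(IMG)^2) / n^2)
    IMGB <- IMG[crop, crop]
    imgb_norm <- sqrt(sum(Mod(IMGB)^2) / nb^2)
    step0 <- if (method == "exhaustive") max(polish_step, 0.25) else angular_step
    centred <- function(width, st) { # symmetric offsets that include 0
      off <- seq(0, width, by = st)
      sort(unique(c(-off, off)))
    }
    cand <- expand.grid(
      rot = seq(0, 360 - step0, step0),
      tilt = 90 + centred(tilt_width, step0),
      psi = sg$psi_prior + centred(psi_width, step0))
    if (method == "exhaustive") {
      best <- match_candidates(IMG, img_norm, prj, sg$ctf, cand, max_shift_px)
    } else {
      best <- match_candidates(IMGB, imgb_norm, prjB, sg$ctf, cand,
                               max_shift_px / bin)
      stages <- polish_schedule(angular_step, polish_step)
      n_binned <- if (full_polish && bin > 1L) length(stages) - 1L else length(stages)
      if (n_binned > 0L) {
        pol <- refine_pose_local(IMGB, imgb_norm, prjB, sg$ctf, best$pose,
                                 stages[seq_len(n_binned)], max_shift_px / bin)
        if (!is.null(pol)) best <- pol
      }
      if (full_polish && bin > 1L) {
        fin <- refine_pose_local(IMG, img_norm, prj, sg$ctf, best$pose,
                                 stages[length(stages)], max_shift_px)
        if (!is.null(fin)) best <- fin
      }
    }
    rows[[i]] <- best$pose
    scores[i] <- best$score
  }
  list(poses = do.call(rbind, rows), scores = scores)
}

# Halving schedule from coarse step down to fine_step: each stage searches
# +/- its step about the running best (the previous stage's step bounds the
# residual error).
polish_schedule <- function(coarse, fine) {
  steps <- list(list(range = coarse, step = coarse / 2))
  s <- coarse / 4
  while (s >= fine) {
    steps[[length(steps) + 1L]] <- list(range = s, step = s)
    s <- s / 2
  }
  if (steps[[length(steps)]]$step > fine)
    steps[[length(steps) + 1L]] <- list(range = fine, step = fine)
  steps
}

#' Iterative consensus refinement of filament segments
#'
#' Alternates [align_segments()] and [reconstruct()] starting from an
#' initial volume (a low-passed reference map or a featureless cylinder).
#' Segments scoring below the `score_quantile` quantile in the final
#' iteration are marked rejected and excluded from the returned map, a
#' stand-in for the 2D/3D classification cleanup used in practice. If
#' `initial_poses` is supplied the first iteration reconstructs directly
#' from them (alignment bootstrap).
#'
#' @param segments list of `segment_particle`s.
#' @param initial a [density_map()] initial reference.
#' @param n_iter number of iterations (>= 1).
#' @param score_quantile fraction of worst-scoring segments to reject.
#' @param wiener passed to [reconstruct()].
#' @param initial_poses optional pose data.frame bootstrap.
#' @param ref_lowpass reference filtering between iterations: `"fsc"`
#'   (default) filters at the gold-standard half-map resolution measured by
#'   a filament-wise split — aligning against an unfiltered reconstruction
#'   locks poses onto its noise; a number fixes the resolution (Angstrom);
#'   `NULL` disables filtering.
#' @param ... passed to [align_segments()].
#' @return list with `map` (consensus [density_map()]), `poses`, `scores`,
#'   `status` (active/rejected per segment), `history` (per-iteration mean
#'   score and correlation to the initial reference).
#' @export
iterate_consensus <- function(segments, initial, n_iter = 3,
                              score_quantile = 0.1, wiener = NULL,
                              initial_poses = NULL, ref_lowpass = "fsc", ...) {
  if (n_iter < 1) stop("iterate_consensus: n_iter must be >= 1")
  ref <- initial
  poses <- initial_poses
  scores <- rep(NA_real_, length(segments))
  history <- data.frame()
  imgs <- lapply(segments, `[[`, "image")
  ctfs <- lapply(segments, `[[`, "ctf")
  if (all(vapply(ctfs, is.null, logical(1)))) ctfs <- NULL
  map <- NULL
  prev_mean <- NULL
  fids <- vapply(segments, function(s) as.character(s$filament_id), character(1))
  ref_res <- NA_real_
  for (it in seq_len(n_iter)) {
    if (it == 1L && !is.null(initial_poses)) {
      map <- reconstruct(imgs, initial_poses, ctfs, wiener)
    } else {
      ar <- if (is.null(ref_lowpass) || (it == 1L)) ref
      else if (identical(ref_lowpass, "fsc")) {
        if (is.finite(ref_res)) lowpass(ref, ref_res) else ref
      } else lowpass(ref, ref_lowpass)
      # intermediate iterations only shape the reference: binned polish is
      # enough there; the final pass polishes at full sampling
      args <- list(segments = segments, reference = ar, ...)
      if (it < n_iter && is.null(args$full_polish)) args$full_polish <- FALSE
      res <- do.call(align_segments, args)
      poses <- res$poses
      scores <- res$scores
      if (!is.null(prev_mean) && mean(scores) < 0.5 * prev_mean)
        stop("iterate_consensus: score collapse (mean NCC ",
             signif(mean(scores), 3), " after ", signif(prev_mean, 3),
             "); alignment diverged")
      prev_mean <- mean(scores)
      map <- reconstruct(imgs, poses, ctfs, wiener)
    }
    if (identical(ref_lowpass, "fsc") && it < n_iter && !is.null(poses) &&
        length(unique(fids)) >= 2L) {
      ha_ids <- unique(fids)[c(TRUE, FALSE)]
      ia <- fids %in% ha_ids
      ref_res <- gold_standard_resolution(
        reconstruct(imgs[ia], poses[ia, , drop = FALSE],
                    if (is.null(ctfs)) NULL else ctfs[ia], wiener),
        reconstruct(imgs[!ia], poses[!ia, , drop = FALSE],
                    if (is.null(ctfs)) NULL else ctfs[!ia], wiener))
    }
    history <- rbind(history, data.frame(
      iter = it,
      mean_score = mean(scores),
      resolution = ref_res,
      corr_initial = stats::cor(as.vector(map$values), as.vector(initial$values))))
    ref <- map
  }
  status <- rep("active", length(segments))
  if (!all(is.na(scores)) && score_quantile > 0) {
    cut <- stats::quantile(scores, score_quantile, na.rm = TRUE)
    status[scores < cut] <- "rejected"
    if (any(status == "rejected")) {
      keep <- status == "active"
      map <- reconstruct(imgs[keep], poses[keep, , drop = FALSE],
                         if (is.null(ctfs)) NULL else ctfs[keep], wiener)
    }
  }
  list(map = map, poses = poses, scores = scores, status = status,
       history = history)
}
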
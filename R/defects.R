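# Detection of +-1/2 nematic defects from Q fields via the charge-density
# formula, a winding-number oracle, trajectory linking, and kth-nearest-
# neighbour opposite-charge distances.

#' Topological charge density of a Q field
#'
#' q = (1/4 pi) * sum_k (dQxk/dx * dQyk/dy - dQyk/dx * dQxk/dy) with k running
#' over {x, y}, evaluated by centred differences in node units so that the sum
#' of q over a defect core approximates the enclosed topological charge.
#' On bounded grids the one-node boundary ring is masked.
#'
#' @param q_field a `q_field` (see [director_to_q()]).
#' @param periodic treat the grid as periodic (no boundary masking).
#' @return object of class `charge_density_field` with matrix `q`, `spacing`
#'   (um) and `mask`.
#' @export
charge_density <- function(q_field, periodic = FALSE) {
  stopifnot(inherits(q_field, "q_field"))
  qxx <- q_field$qxx; qxy <- q_field$qxy
  if (nrow(qxx) < 3 || ncol(qxx) < 3) stop("grid too small for centred differences")
  if (periodic) {
    dx <- ddx_periodic; dy <- ddy_periodic
  } else {
    dx <- ddx_bounded; dy <- ddy_bounded
  }
  # Qxx = qxx, Qxy = Qyx = qxy, Qyy = -qxx (2D traceless symmetric part)
  qxx_x <- dx(qxx); qxx_y <- dy(qxx)
  qxy_x <- dx(qxy); qxy_y <- dy(qxy)
  # k = x: dQxx/dx dQyx/dy - dQyx/dx dQxx/dy
  tx <- qxx_x * qxy_y - qxy_x * qxx_y
  # k = y: dQxy/dx dQyy/dy - dQyy/dx dQxy/dy
  ty <- qxy_x * (-qxx_y) - (-qxx_x) * qxy_y
  q <- (tx + ty) / (4 * pi)
  mask <- is.finite(q) & q_field$mask
  q[!mask] <- NA_real_
  structure(list(q = q, spacing = q_field$spacing, mask = mask,
                 time = q_field$time),
            class = "charge_density_field")
}

#' Detect half-integer defects from a charge-density field
#'
#' Candidate nodes are every `subsample`-th node with |q| above `threshold`;
#' candidates of equal sign are grouped into connected cores (8-connectivity
#' on the subsampled grid), one defect per core at the |q|-weighted centroid,
#' with charge sign(q at the core peak) * 1/2. Cores of equal sign closer
#' than `min_separation` are merged.
#'
#' @param q a `charge_density_field`.
#' @param threshold detection threshold on |q| (default 0.1).
#' @param subsample consider every `subsample`-th node (default 5).
#' @param min_separation merge distance in micrometres (default twice the
#'   subsampled node spacing).
#' @param frame frame index attached to the detections.
#' @return data.frame with columns x_um, y_um, charge, q_peak, frame
#'   (zero rows when nothing is detected).
#' @export
detect_defects <- function(q, threshold = 0.1, subsample = 5,
                           min_separation = NULL, frame = 0L) {
  stopifnot(inherits(q, "charge_density_field"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (subsample < 1) stop("subsample must be >= 1")
  sub_i <- seq(1L, nrow(q$q), by = subsample)
  sub_j <- seq(1L, ncol(q$q), by = subsample)
  qs <- q$q[sub_i, sub_j, drop = FALSE]
  ms <- q$mask[sub_i, sub_j, drop = FALSE]
  spacing_sub <- q$spacing * subsample
  if (is.null(min_separation)) min_separation <- 2 * spacing_sub

  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      charge = numeric(0), q_peak = numeric(0),
                      frame = integer(0))
  out <- empty
  for (sgn in c(1, -1)) {
    hit <- ms & is.finite(qs) & (sgn * qs > threshold)
    if (!any(hit)) next
    lab <- EBImage::bwlabel(matrix(as.numeric(hit), nrow(qs), ncol(qs)))
    nlab <- max(lab)
    cores <- lapply(seq_len(nlab), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      w <- abs(qs[idx])
      peak <- idx[which.max(w), , drop = FALSE]
      data.frame(
        x_um = sum((sub_j[idx[, 2]] - 1) * w) / sum(w) * q$spacing,
        y_um = sum((sub_i[idx[, 1]] - 1) * w) / sum(w) * q$spacing,
        charge = sgn * 0.5,
        q_peak = qs[peak],
        weight = sum(w))
    })
    cores <- do.call(rbind, cores)
    cores <- merge_close_cores(cores, min_separation)
    cores$weight <- NULL
    out <- rbind(out, cores)
  }
  if (nrow(out)) {
    out$frame <- as.integer(frame)
    out <- out[order(out$y_um, out$x_um), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Merge same-sign cores closer than min_sep (weighted average position,
# strongest peak kept). Iterates until stable.
merge_close_cores <- function(cores, min_sep) {
  repeat {
    n <- nrow(cores)
    if (n < 2) return(cores)
    d <- as.matrix(stats::dist(cores[, c("x_um", "y_um")]))
    diag(d) <- Inf
    hit <- which(d < min_sep, arr.ind = TRUE)
    if (!nrow(hit)) return(cores)
    i <- hit[1, 1]; j <- hit[1, 2]
    w <- cores$weight[c(i, j)]
    merged <- cores[i, , drop = FALSE]
    merged$x_um <- sum(cores$x_um[c(i, j)] * w) / sum(w)
    merged$y_um <- sum(cores$y_um[c(i, j)] * w) / sum(w)
    keep <- which.max(abs(cores$q_peak[c(i, j)]))
    merged$q_peak <- cores$q_peak[c(i, j)][keep]
    merged$weight <- sum(w)
    cores <- rbind(cores[-c(i, j), , drop = FALSE], merged)
  }
}

#' Winding number of the director around a closed loop
#'
#' Samples the director angle along a circle, accumulates successive angle
#' differences wrapped into (-pi/2, pi/2], and divides by 2 pi. The result is
#' rounded to the nearest multiple of 1/2; the pre-rounding residual must be
#' below 0.1 or an error is raised (ill-conditioned loop, e.g. a core sitting
#' on it). Used as the independent topological oracle for the charge-density
#' detector.
#'
#' @param field a [director_field()].
#' @param loop_center numeric (x, y) centre in micrometres.
#' @param loop_radius radius in micrometres.
#' @param n_samples number of loop samples (>= 16).
#' @return half-integer winding number, with attribute `residual`.
#' @export
winding_number <- function(field, loop_center, loop_radius, n_samples = 64) {
  stopifnot(inherits(field, "director_field"))
  if (n_samples < 16) stop("n_samples must be >= 16")
  h <- field$spacing
  th <- seq(0, 2 * pi, length.out = n_samples + 1)
  cx <- loop_center[1] / h + 1; cy <- loop_center[2] / h + 1
  ri <- cy + (loop_radius / h) * sin(th)
  ci <- cx + (loop_radius / h) * cos(th)
  if (any(ri < 1 | ri > nrow(field$alpha) | ci < 1 | ci > ncol(field$alpha)))
    stop("loop exits the grid")
  # sample the director through its double angle so that interpolation
  # respects the nematic (mod pi) identification
  c2 <- bilinear(cos(2 * field$alpha), ri, ci)
  s2 <- bilinear(sin(2 * field$alpha), ri, ci)
  a <- 0.5 * atan2(s2, c2)
  da <- fold_half(diff(a))
  w_raw <- sum(da) / (2 * pi)
  w <- round(w_raw * 2) / 2
  residual <- abs(w_raw - w)
  if (residual >= 0.1)
    stop(sprintf("winding residual %.3f >= 0.1: ill-conditioned loop", residual))
  structure(w, residual = residual)
}

#' Link per-frame defect detections into trajectories
#'
#' Greedy globally-smallest-distance frame-to-frame assignment, restricted to
#' equal charges and displacements at most `max_displacement`, with gap
#' closing up to `max_gap` frames. Tracks present for less than
#' `min_duration` hours are discarded.
#'
#' @param detections data.frame as returned by [detect_defects()] (columns
#'   x_um, y_um, charge, frame; multiple frames stacked) or a list of
#'   per-frame data.frames.
#' @param max_displacement maximum step in micrometres per frame.
#' @param max_gap maximum number of skipped frames bridged by one link.
#' @param min_duration minimum track duration in hours (default 4).
#' @param frame_interval_h hours per frame (default 1/3, i.e. 20 min).
#' @return data.frame of tracked detections with a `track_id` column and
#'   per-track `duration_h`; tracks failing the duration filter are dropped.
#' @export
link_trajectories <- function(detections, max_displacement, max_gap = 0,
                              min_duration = 4, frame_interval_h = 1 / 3) {
  if (is.list(detections) && !is.data.frame(detections))
    detections <- do.call(rbind, detections)
  if (max_displacement <= 0) stop("max_displacement must be > 0")
  if (!nrow(detections)) {
    detections$track_id <- integer(0); detections$duration_h <- numeric(0)
    return(detections)
  }
  frames <- sort(unique(detections$frame))
  if (is.unsorted(frames)) stop("frames must be ordered")
  detections <- detections[order(detections$frame), , drop = FALSE]
  detections$.row <- seq_len(nrow(detections))
  detections$track_id <- NA_integer_
  # active track heads: track_id, x, y, charge, last_frame
  heads <- data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                      charge = numeric(0), last_frame = integer(0))
  next_id <- 1L
  for (f in frames) {
    cur <- detections[detections$frame == f, , drop = FALSE]
    heads <- heads[f - heads$last_frame <= max_gap + 1L, , drop = FALSE]
    assigned_det <- rep(FALSE, nrow(cur))
    used_head <- rep(FALSE, nrow(heads))
    if (nrow(heads) && nrow(cur)) {
      cand <- expand.grid(h = seq_len(nrow(heads)), d = seq_len(nrow(cur)))
      cand <- cand[heads$charge[cand$h] == cur$charge[cand$d], , drop = FALSE]
      if (nrow(cand)) {
        cand$dist <- sqrt((heads$x[cand$h] - cur$x_um[cand$d])^2 +
                          (heads$y[cand$h] - cur$y_um[cand$d])^2)
        gap <- f - heads$last_frame[cand$h]  # >= 1
        cand <- cand[cand$dist <= max_displacement * gap, , drop = FALSE]
        cand <- cand[order(cand$dist), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          h <- cand$h[r]; d <- cand$d[r]
          if (used_head[h] || assigned_det[d]) next
          used_head[h] <- TRUE; assigned_det[d] <- TRUE
          detections$track_id[cur$.row[d]] <- heads$track_id[h]
          heads$x[h] <- cur$x_um[d]; heads$y[h] <- cur$y_um[d]
          heads$last_frame[h] <- f
        }
      }
    }
    if (any(!assigned_det)) {
      new <- cur[!assigned_det, , drop = FALSE]
      ids <- seq.int(next_id, length.out = nrow(new))
      next_id <- next_id + nrow(new)
      detections$track_id[new$.row] <- ids
      heads <- rbind(heads, data.frame(track_id = ids, x = new$x_um,
                                       y = new$y_um, charge = new$charge,
                                       last_frame = f))
    }
  }
  detections$.row <- NULL
  span <- tapply(detections$frame, detections$track_id,
                 function(fr) (max(fr) - min(fr) + 1L) * frame_interval_h)
  detections$duration_h <- as.numeric(span[as.character(detections$track_id)])
  out <- detections[detections$duration_h >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' kth-nearest-neighbour distances between opposite-charge defects
#'
#' For every defect in every frame, the distances to its (k+1)-closest
#' defects of opposite charge, for k in `k_list`; per-frame mean and standard
#' deviation per k. Frames with too few opposite-charge defects yield NA
#' entries (flagged, never zero-filled).
#'
#' @param detections data.frame of detections (possibly tracked) with columns
#'   x_um, y_um, charge, frame.
#' @param k_list neighbour orders (default 0:3).
#' @return list with `per_defect` (frame, charge, x_um, y_um, k, d_um) and
#'   `summary` (frame, k, mean_um, std_um, n_pairs).
#' @export
knn_opposite_distances <- function(detections, k_list = 0:3) {
  frames <- sort(unique(detections$frame))
  per <- list(); summ <- list()
  for (f in frames) {
    cur <- detections[detections$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(cur))) {
      opp <- cur[cur$charge == -cur$charge[i], , drop = FALSE]
      d <- sort(sqrt((opp$x_um - cur$x_um[i])^2 + (opp$y_um - cur$y_um[i])^2))
      dk <- ifelse(k_list + 1 <= length(d), d[pmin(k_list + 1, length(d))], NA_real_)
      per[[length(per) + 1]] <- data.frame(
        frame = f, charge = cur$charge[i], x_um = cur$x_um[i],
        y_um = cur$y_um[i], k = k_list, d_um = dk)
    }
    cur_per <- do.call(rbind, per[seq.int(length(per) - nrow(cur) + 1,
                                          length.out = nrow(cur))])
    if (is.null(cur_per)) cur_per <- data.frame(frame = numeric(0), k = numeric(0), d_um = numeric(0))
    for (k in k_list) {
      dk <- cur_per$d_um[cur_per$k == k]
      dk_ok <- dk[is.finite(dk)]
      summ[[length(summ) + 1]] <- data.frame(
        frame = f, k = k,
        mean_um = if (length(dk_ok)) mean(dk_ok) else NA_real_,
        std_um = if (length(dk_ok) > 1) stats::sd(dk_ok) else NA_real_,
        n_pairs = length(dk_ok))
    }
  }
  list(per_defect = if (length(per)) do.call(rbind, per) else
         data.frame(frame = numeric(0), charge = numeric(0), x_um = numeric(0),
                    y_um = numeric(0), k = numeric(0), d_um = numeric(0)),
       summary = do.call(rbind, summ))
}

#' Topologically exact defect detection by plaquette winding
#'
#' Accumulates nematic-wrapped angle differences around every unit plaquette
#' of the (periodic) grid; the winding around a plaquette is quantized in
#' units of pi, and each plaquette with winding +-pi encloses exactly one
#' +-1/2 defect (winding is additive, so neighbouring defects occupy
#' distinct plaquettes). The total detected charge on a periodic domain is
#' therefore exactly zero; this is the preferred detector for simulated Q
#' fields, whose annihilating cores can be too smeared for a fixed
#' charge-density threshold.
#'
#' @param field a [director_field()] on a periodic grid.
#' @param frame frame index attached to the detections.
#' @return data.frame with columns x_um, y_um, charge (plaquette winding /
#'   2 pi), q_peak (raw winding / 2 pi) and frame.
#' @export
detect_defects_winding <- function(field, frame = 0L) {
  a <- field$alpha
  n1 <- nrow(a); n2 <- ncol(a)
  wrap <- function(x) (x + pi / 2) %% pi - pi / 2
  ar <- a[, c(2:n2, 1)]          # right neighbour
  ad <- a[c(2:n1, 1), ]          # down neighbour
  ard <- a[c(2:n1, 1), c(2:n2, 1)]
  w <- wrap(ar - a) + wrap(ard - ar) - wrap(ard - ad) - wrap(ad - a)
  q <- round(w / pi) / 2         # plaquette charge in halves
  idx <- which(q != 0, arr.ind = TRUE)
  out <- data.frame(
    x_um = (idx[, 2] - 0.5) * field$spacing,
    y_um = (idx[, 1] - 0.5) * field$spacing,
    charge = q[idx], q_peak = w[idx] / (2 * pi),
    frame = rep(as.integer(frame), nrow(idx)))
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}
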
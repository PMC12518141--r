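# Identification and length measurement of the parallel ("green", low-energy)
# and perpendicular ("red", high-energy) domain-wall strings: discontinuity
# lines of the two director-angle representations.

#' Dual angle representations of a director field
#'
#' The director n = (cos a, sin a) is represented both with
#' alpha1 in [0, pi) (first and second vector quadrants) and
#' alpha2 in (-pi/2, pi/2] (first and fourth). A director crossing the
#' preferred axis is continuous in alpha2 but jumps in alpha1, and vice versa
#' for a director crossing the perpendicular orientation; the jump lines of
#' the two maps are the green and red strings.
#'
#' @param field a [director_field()].
#' @return object of class `angle_maps` with matrices `alpha1`, `alpha2`,
#'   plus `mask` and `spacing`.
#' @export
dual_angle_maps <- function(field) {
  stopifnot(inherits(field, "director_field"))
  alpha2 <- field$alpha              # native (-pi/2, pi/2]
  alpha1 <- field$alpha %% pi        # [0, pi)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, mask = field$mask,
                 spacing = field$spacing, time = field$time),
            class = "angle_maps")
}

#' Binary string maps from angle-representation jumps
#'
#' For every 4-neighbour pair of valid nodes, a green edge is marked when
#' |delta alpha1| exceeds `jump_threshold` and a red edge when
#' |delta alpha2| does. Each jump edge marks both incident nodes in the
#' rasterized binary map.
#'
#' @param maps an `angle_maps` object.
#' @param jump_threshold angle jump threshold in radians (default pi/2).
#' @return object of class `string_map` with logical matrices `green_map`,
#'   `red_map` and `spacing`.
#' @export
string_maps <- function(maps, jump_threshold = pi / 2) {
  stopifnot(inherits(maps, "angle_maps"))
  if (jump_threshold <= 0 || jump_threshold >= pi)
    stop("jump_threshold must lie in (0, pi)")
  mark <- function(a) {
    out <- matrix(FALSE, nrow(a), ncol(a))
    va <- maps$mask
    # horizontal neighbours
    dh <- abs(a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE])
    jh <- dh > jump_threshold & va[, -1, drop = FALSE] & va[, -ncol(a), drop = FALSE]
    out[, -1] <- out[, -1] | jh
    out[, -ncol(a)] <- out[, -ncol(a)] | jh
    # vertical neighbours
    dv <- abs(a[-1, , drop = FALSE] - a[-nrow(a), , drop = FALSE])
    jv <- dv > jump_threshold & va[-1, , drop = FALSE] & va[-nrow(a), , drop = FALSE]
    out[-1, ] <- out[-1, ] | jv
    out[-nrow(a), ] <- out[-nrow(a), ] | jv
    out
  }
  structure(list(green_map = mark(maps$alpha1), red_map = mark(maps$alpha2),
                 spacing = maps$spacing, time = maps$time),
            class = "string_map")
}

#' Skeletonize string maps and measure per-string lengths
#'
#' Connected components (8-connectivity) of each binary map are thinned to
#' unit-width skeletons (Zhang-Suen); the length of a string is the total
#' edge length of its skeleton chain, counting orthogonal steps as `spacing`
#' and diagonal steps as `spacing * sqrt(2)`. Components smaller than
#' `min_nodes` nodes are discarded as noise.
#'
#' @param map a `string_map`.
#' @param spacing node spacing in micrometres (defaults to the map's own).
#' @param min_nodes minimum component size in nodes (default 3).
#' @return object of class `string_set`: data.frame `strings` (class,
#'   string_id, length_um, n_nodes) with skeleton node lists in attribute
#'   `skeletons`, and `summary` (class, median_um, iqr_low, iqr_high,
#'   n_strings; NA medians flag empty classes).
#' @export
measure_strings <- function(map, spacing = NULL, min_nodes = 3) {
  stopifnot(inherits(map, "string_map"))
  if (is.null(spacing)) spacing <- map$spacing
  res <- list(); skels <- list()
  for (cls in c("green", "red")) {
    bin <- if (cls == "green") map$green_map else map$red_map
    if (!any(bin)) next
    lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      if (sum(comp) < min_nodes) next
      sk <- thin_zhang_suen(comp)
      len <- skeleton_length(sk, spacing)
      id <- length(res) + 1L
      res[[id]] <- data.frame(class = cls, string_id = id,
                              length_um = len, n_nodes = sum(sk))
      skels[[id]] <- which(sk, arr.ind = TRUE)
    }
  }
  strings <- if (length(res)) do.call(rbind, res) else
    data.frame(class = character(0), string_id = integer(0),
               length_um = numeric(0), n_nodes = integer(0))
  summ <- do.call(rbind, lapply(c("green", "red"), function(cls) {
    v <- strings$length_um[strings$class == cls]
    if (length(v)) {
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cls, median_um = qs[2], iqr_low = qs[1],
                 iqr_high = qs[3], n_strings = length(v))
    } else {
      data.frame(class = cls, median_um = NA_real_, iqr_low = NA_real_,
                 iqr_high = NA_real_, n_strings = 0L)
    }
  }))
  structure(list(strings = strings, summary = summ, skeletons = skels,
                 spacing = spacing, time = map$time),
            class = "string_set")
}

#' @export
print.string_set <- function(x, ...) {
  cat("<string_set>\n"); print(x$summary); invisible(x)
}

# Zhang-Suen binary thinning to a unit-width skeleton.
thin_zhang_suen <- function(bin) {
  img <- matrix(0L, nrow(bin) + 2, ncol(bin) + 2)
  img[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)] <- as.integer(bin)
  nbr <- function(img) {
    # 8 neighbours in Zhang-Suen order p2..p9 (N, NE, E, SE, S, SW, W, NW)
    n1 <- nrow(img); n2 <- ncol(img)
    core <- function(di, dj) img[(2 + di):(n1 - 1 + di), (2 + dj):(n2 - 1 + dj)]
    list(p2 = core(-1, 0), p3 = core(-1, 1), p4 = core(0, 1), p5 = core(1, 1),
         p6 = core(1, 0), p7 = core(1, -1), p8 = core(0, -1), p9 = core(-1, -1))
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- nbr(img)
      core <- img[2:(nrow(img) - 1), 2:(ncol(img) - 1)]
      B <- p$p2 + p$p3 + p$p4 + p$p5 + p$p6 + p$p7 + p$p8 + p$p9
      seqp <- list(p$p2, p$p3, p$p4, p$p5, p$p6, p$p7, p$p8, p$p9, p$p2)
      A <- Reduce(`+`, lapply(1:8, function(i) (seqp[[i]] == 0) & (seqp[[i + 1]] == 1)))
      if (pass == 1) {
        c1 <- p$p2 * p$p4 * p$p6; c2 <- p$p4 * p$p6 * p$p8
      } else {
        c1 <- p$p2 * p$p4 * p$p8; c2 <- p$p2 * p$p6 * p$p8
      }
      del <- core == 1L & B >= 2 & B <= 6 & A == 1 & c1 == 0 & c2 == 0
      if (any(del)) {
        changed <- TRUE
        core[del] <- 0L
        img[2:(nrow(img) - 1), 2:(ncol(img) - 1)] <- core
      }
    }
    if (!changed) break
  }
  img[2:(nrow(img) - 1), 2:(ncol(img) - 1)] == 1L
}

# Total length of a skeleton: minimum-spanning-tree edge length of the
# 8-neighbour adjacency graph (orthogonal edge = spacing, diagonal =
# spacing * sqrt(2)). For chain-like skeletons this is the chain length.
skeleton_length <- function(sk, spacing) {
  pix <- which(sk, arr.ind = TRUE)
  n <- nrow(pix)
  if (n <= 1) return(0)
  edges <- NULL; weights <- NULL
  key <- pix[, 1] + 1i * pix[, 2]
  idx <- stats::setNames(seq_len(n), as.character(key))
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- (pix[, 1] + d[1]) + 1i * (pix[, 2] + d[2])
    j <- idx[as.character(nb)]
    ok <- !is.na(j)
    if (any(ok)) {
      edges <- rbind(edges, cbind(which(ok), j[ok]))
      w <- if (all(d != 0)) sqrt(2) else 1
      weights <- c(weights, rep(w * spacing, sum(ok)))
    }
  }
  if (is.null(edges)) return(0)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  mst <- igraph::mst(g)
  sum(igraph::E(mst)$weight)
}
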
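# Classical baseline leaf-tip detector:
# excess-green vegetation indexing -> Otsu threshold -> morphological opening
# -> Zhang-Suen skeleton -> endpoint extraction -> taper-based tip
# classification. It is a desk-scale stand-in satisfying the same plug-in
# contract as any external (deep) detector: image in, scored 12 x 12 boxes
# out, serialised in the shared COCO/CSV dialect.

#' Excess-green vegetation mask
#'
#' Computes the excess-green index ExG = 2G - R - B per pixel, thresholds it
#' with Otsu's method on the ExG histogram, and applies a radius-1
#' morphological opening. ExG is scale-equivariant: multiplying all channels
#' by c > 0 scales ExG by c and preserves the Otsu split.
#'
#' Two refinements target the sub-pixel-thin distal blade, whose mixed
#' pixels fall below the Otsu split: hysteresis (pixels above
#' `hysteresis_low` times the Otsu level join if 8-connected to an
#' above-threshold region) and opening by reconstruction (the opening
#' decides which connected components survive, but survivors are kept whole
#' rather than eroded). Set `hysteresis_low = 1` for the plain Otsu split.
#'
#' @param rgb H x W x 3 array (any common scale).
#' @param hysteresis_low Weak-threshold fraction of the Otsu level, in
#'   (0, 1].
#' @return A logical H x W matrix (TRUE = vegetation).
#' @export
vegetation_mask <- function(rgb, hysteresis_low = 0.4) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    abort("`rgb` must be a 3-channel image array.",
          class = "wheattips_invalid_parameter")
  exg <- 2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
  rng <- range(exg)
  if (diff(rng) < 1e-12) {
    warn("Constant image: degenerate ExG histogram, returning an empty mask.",
         class = "wheattips_degenerate_image")
    return(matrix(FALSE, nrow(exg), ncol(exg)))
  }
  norm <- (exg - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  strong <- norm > thr
  # hysteresis: weak pixels count only when attached to a strong region
  zero_level <- -rng[1] / diff(rng)  # normalized position of ExG == 0
  low <- zero_level + hysteresis_low * (thr - zero_level)
  weak <- norm > low
  if (!any(strong)) {
    warn("No pixel above the Otsu split; returning an empty mask.",
         class = "wheattips_degenerate_image")
    return(matrix(FALSE, nrow(exg), ncol(exg)))
  }
  wl <- EBImage::bwlabel(weak * 1)
  mask <- weak & (wl %in% unique(wl[strong & wl > 0]))
  # opening by reconstruction: the radius-1 opening decides which connected
  # components survive (killing isolated specks), but surviving components
  # are kept whole so the thin distal blade is not clipped off
  opened <- EBImage::opening(mask * 1, EBImage::makeBrush(3, "disc")) > 0.5
  if (!any(opened)) return(matrix(FALSE, nrow(exg), ncol(exg)))
  labels <- EBImage::bwlabel(mask * 1)
  keep <- unique(labels[opened & labels > 0])
  out <- matrix(labels %in% keep & mask, nrow(exg), ncol(exg))
  out <- fill_small_holes(out, max_area = 64)
  # the plain Otsu split ("core") carries the blade-width taper that the
  # hysteresis halo smooths away; the classifier uses it when present
  attr(out, "core") <- matrix(strong & out, nrow(exg), ncol(exg))
  # the normalized ExG field and its reference levels let the classifier
  # trace the sub-threshold tail beyond the mask end
  attr(out, "exg") <- norm
  attr(out, "exg_levels") <- c(zero = zero_level, otsu = thr)
  out
}

# Fill enclosed background regions up to `max_area` px: speckle holes from
# partial pixel coverage would otherwise leave loops in the skeleton (and no
# endpoint at the tip), while genuinely enclosed soil stays open.
fill_small_holes <- function(mask, max_area = 64) {
  bg <- EBImage::bwlabel((!mask) * 1)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  tab <- tabulate(bg[bg > 0])
  fill <- setdiff(which(tab <= max_area), border_labels)
  if (length(fill) > 0) mask[bg %in% fill] <- TRUE
  mask
}

# 8-connected neighbour count of each TRUE pixel in a binary matrix.
neighbour_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m * 1L
  s <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  s
}

# Crossing number: 0->1 transitions around the 8-neighbour ring (clockwise).
crossing_number <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m * 1L
  sh <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  ring <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  A <- matrix(0L, H, W)
  for (k in 1:8) {
    nxt <- ring[[if (k == 8) 1 else k + 1]]
    A <- A + (ring[[k]] == 0L & nxt == 1L)
  }
  A
}

#' Skeleton endpoints of a binary mask
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen) and returns the skeleton
#' pixels having exactly one 8-connected skeleton neighbour. With
#' `prune > 0`, side spurs shorter than `prune` pixels (thinning barbs on
#' ragged blades) are removed first, which merges their junctions back into
#' the main branch.
#'
#' @param mask Logical H x W matrix.
#' @param prune Remove spurs shorter than this many pixels (0 = keep all).
#' @return A list with `skeleton` (logical matrix) and `endpoints`, a tibble
#'   of 0-based pixel coordinates (`u` = column, `v` = row).
#' @export
skeleton_endpoints <- function(mask, prune = 0L) {
  if (!any(mask))
    return(list(skeleton = mask & FALSE,
                endpoints = tibble(u = integer(), v = integer())))
  skel <- cpp_thin(matrix(as.integer(mask), nrow(mask), ncol(mask))) > 0
  if (prune > 0) skel <- prune_spurs(skel, prune)
  nb <- neighbour_count(skel)
  # one neighbour, or two mutually adjacent neighbours forming a single arc
  # (crossing number 1): thinning leaves such doubled pixels at the ends of
  # diagonal staircases
  A <- crossing_number(skel)
  idx <- which(skel & nb >= 1 & nb <= 2 & A == 1, arr.ind = TRUE)
  list(skeleton = skel,
       endpoints = tibble(u = as.integer(idx[, 2] - 1L),
                          v = as.integer(idx[, 1] - 1L)))
}

# Iteratively delete endpoint branches that run into a junction in fewer
# than `min_len` pixels (the junction pixel itself is kept).
prune_spurs <- function(skel, min_len, max_iter = 3L) {
  for (it in seq_len(max_iter)) {
    nb <- neighbour_count(skel)
    idx <- which(skel & nb == 1, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(idx))) {
      r0 <- idx[i, 1]; c0 <- idx[i, 2]
      if (!skel[r0, c0]) next
      branch <- walk_branch(skel, r0, c0, min_len + 1L)
      if (nrow(branch) > min_len) next          # long enough: keep
      last <- branch[nrow(branch), , drop = FALSE]
      if (nb[last] <= 2) next                   # short isolated segment
      skel[branch[-nrow(branch), , drop = FALSE]] <- FALSE  # barb
      removed <- TRUE
    }
    if (!removed) break
  }
  skel
}

# Walk along the skeleton from an endpoint, up to `limit` pixels or until a
# junction; returns the branch as 1-based (row, col) matrix incl. endpoint.
walk_branch <- function(skel, r0, c0, limit) {
  H <- nrow(skel); W <- ncol(skel)
  branch <- matrix(c(r0, c0), 1, 2)
  visited <- new.env(hash = TRUE)
  assign(sprintf("%d_%d", r0, c0), TRUE, envir = visited)
  r <- r0; c <- c0
  while (nrow(branch) < limit) {
    nxt <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (!skel[rr, cc]) next
      if (exists(sprintf("%d_%d", rr, cc), envir = visited)) next
      nxt <- rbind(nxt, c(rr, cc))
    }
    if (is.null(nxt)) break  # dead end
    if (nrow(nxt) == 2 &&
        max(abs(nxt[1, ] - nxt[2, ])) <= 1) {
      # doubled staircase pixel: absorb both, continue along one
      assign(sprintf("%d_%d", nxt[2, 1], nxt[2, 2]), TRUE, envir = visited)
      nxt <- nxt[1, , drop = FALSE]
    }
    if (nrow(nxt) != 1) break  # junction
    r <- nxt[1, 1]; c <- nxt[1, 2]
    branch <- rbind(branch, c(r, c))
    assign(sprintf("%d_%d", r, c), TRUE, envir = visited)
  }
  branch
}

#' Classify skeleton endpoints as leaf tips
#'
#' An endpoint is kept iff its local blade tapers: the distance-transform
#' value at the endpoint must be smaller than `taper_ratio` times the median
#' distance-transform value along the first `branch_window` pixels of its
#' incident skeleton branch. Branches shorter than `min_branch` pixels are
#' rejected (isolated specks). The detection score is `1 - ratio`, clamped to
#' \[0, 1\]. The emitted point is refined by extending the endpoint along the
#' branch direction to the mask boundary (thinning retreats a little from
#' true tips).
#'
#' @param endpoints Result of [skeleton_endpoints()] (list with `skeleton`
#'   and `endpoints`), as produced from `mask`.
#' @param mask The binary vegetation mask the skeleton came from.
#' @param gsd Ground sampling distance (mm/px); carried into the output.
#' @param taper_ratio,branch_window,min_branch Classifier tuning (see above).
#' @param box_size Side of the emitted detection boxes (px).
#' @return A detection tibble: `center_u`, `center_v`, `box_x`, `box_y`,
#'   `box_w`, `box_h`, `score`.
#' @export
classify_tips <- function(endpoints, mask, gsd = NA,
                          taper_ratio = 0.6, branch_window = NULL,
                          min_branch = 3, box_size = 12,
                          border_margin = box_size / 2,
                          tip_overshoot_mm = 1) {
  skel <- endpoints$skeleton
  ep <- endpoints$endpoints
  empty <- tibble(center_u = double(), center_v = double(),
                  box_x = double(), box_y = double(),
                  box_w = double(), box_h = double(), score = double())
  if (nrow(ep) == 0) return(empty)
  # the taper develops over a physical distance (~12 mm), so the branch
  # window scales with resolution when the GSD is known
  if (is.null(branch_window))
    branch_window <- if (is.na(gsd)) 15L else max(15L, round(12 / gsd))
  H <- nrow(mask); W <- ncol(mask)
  core <- attr(mask, "core") %||% mask
  dt <- EBImage::distmap(core * 1)
  out <- list()
  for (i in seq_len(nrow(ep))) {
    r0 <- ep$v[i] + 1L; c0 <- ep$u[i] + 1L
    # blades leaving the frame end in non-tip endpoints at the border
    if (ep$u[i] < border_margin || ep$u[i] >= W - border_margin ||
        ep$v[i] < border_margin || ep$v[i] >= H - border_margin) next
    branch <- walk_branch(skel, r0, c0, branch_window)
    if (nrow(branch) < min_branch) next
    d_end <- dt[r0, c0]
    d_branch <- median(dt[branch])
    if (d_branch <= 1.5) {
      # branch lies (almost) wholly outside the core split: an already
      # sub-threshold-thin tail, i.e. maximal taper (specks never get here,
      # the mask reconstruction removed them)
      ratio <- 0.5
    } else {
      ratio <- d_end / d_branch
      if (ratio >= taper_ratio) next
    }
    tip <- refine_tip(mask, branch, r0, c0)
    # the sub-pixel tail continues below the mask threshold: follow the
    # faint ExG ridge past the mask end, else fall back to a fixed nudge
    # toward the predicted zero-width point
    k2 <- min(8, nrow(branch))
    dirv <- c(tip[1] - (branch[k2, 2] - 1), tip[2] - (branch[k2, 1] - 1))
    nv <- sqrt(sum(dirv^2))
    if (nv > 0) {
      dirv <- dirv / nv
      exg <- attr(mask, "exg")
      lv <- attr(mask, "exg_levels")
      if (!is.null(exg) && !is.null(lv)) {
        tip <- trace_exg_tail(exg, lv, tip, dirv)
      } else {
        over <- if (!is.na(gsd)) tip_overshoot_mm / gsd else {
          slope <- taper_slope(dt, branch)
          if (is.finite(slope) && slope > 0.01) min(6, 0.15 / slope) else 0
        }
        tip <- tip + dirv * over
      }
    }
    out[[length(out) + 1]] <- tibble(
      center_u = tip[1], center_v = tip[2],
      box_x = tip[1] - box_size / 2, box_y = tip[2] - box_size / 2,
      box_w = box_size, box_h = box_size,
      score = min(max(1 - ratio, 0), 1))
  }
  if (length(out) == 0) return(empty)
  nms_detections(bind_rows(out), radius = box_size / 2)
}

# Thinning and the threshold both retreat from the sub-pixel-thin true tip:
# follow the mask tail beyond the skeleton endpoint by breadth-first search
# restricted to the forward cone of the branch direction, bridging one-pixel
# gaps; the tip is the farthest reached mask pixel.
refine_tip <- function(mask, branch, r0, c0, max_steps = 25) {
  k <- min(8, nrow(branch))
  dir <- c(branch[1, 1] - branch[k, 1], branch[1, 2] - branch[k, 2])
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) return(c(c0 - 1, r0 - 1))
  dir <- dir / nrm
  H <- nrow(mask); W <- ncol(mask)
  frontier <- matrix(c(r0, c0), 1, 2)
  seen <- new.env(hash = TRUE)
  assign(sprintf("%d_%d", r0, c0), TRUE, envir = seen)
  best <- c(r0, c0); best_d <- 0
  for (step in seq_len(max_steps)) {
    nxt <- NULL
    for (q in seq_len(nrow(frontier))) {
      r <- frontier[q, 1]; c <- frontier[q, 2]
      for (dr in -2:2) for (dc in -2:2) {
        if (dr == 0 && dc == 0) next
        if (abs(dr) == 2 && abs(dc) == 1) next  # keep steps compact
        if (abs(dr) == 1 && abs(dc) == 2) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (!mask[rr, cc]) next
        key <- sprintf("%d_%d", rr, cc)
        if (exists(key, envir = seen)) next
        rel <- c(rr - r0, cc - c0)
        if (sum(rel * dir) < -1) next  # stay in the forward cone
        assign(key, TRUE, envir = seen)
        nxt <- rbind(nxt, c(rr, cc))
        proj <- sum(rel * dir)
        if (proj > best_d) { best_d <- proj; best <- c(rr, cc) }
      }
    }
    if (is.null(nxt)) break
    frontier <- nxt
  }
  c(best[2] - 1, best[1] - 1)
}

# Follow the fading excess-green ridge from the mask end toward the true
# tip: advance in half-pixel steps along `dirv`, allowing +-1 px lateral
# ridge tracking, while ExG stays above 10% of the leaf-soil contrast.
trace_exg_tail <- function(exg, lv, tip, dirv, max_ext = 10) {
  H <- nrow(exg); W <- ncol(exg)
  low <- lv["zero"] + 0.1 * (lv["otsu"] - lv["zero"])
  perp <- c(-dirv[2], dirv[1])
  pos <- tip
  best <- tip
  miss <- 0
  for (step in seq(0.5, max_ext, by = 0.5)) {
    ahead <- pos + dirv * 0.5
    cands <- rbind(ahead, ahead + perp, ahead - perp)
    vals <- apply(cands, 1, function(q) {
      cc <- round(q[1]) + 1; rr <- round(q[2]) + 1
      if (rr < 1 || rr > H || cc < 1 || cc > W) -Inf else exg[rr, cc]
    })
    j <- which.max(vals)
    if (vals[j] > low) {
      pos <- cands[j, ]
      best <- pos
      miss <- 0
    } else {
      pos <- ahead
      miss <- miss + 1
      if (miss > 2) break
    }
  }
  # half a pixel beyond the last visible evidence
  best + dirv * 0.5
}

# Half-width decrease per pixel of arc toward the endpoint, from a linear
# fit of the core distance transform along the branch.
taper_slope <- function(dt, branch) {
  vals <- dt[branch]
  arc <- seq_len(nrow(branch)) - 1  # 0 at the endpoint
  use <- vals > 0.5
  if (sum(use) < 4) return(NA_real_)
  stats::coef(stats::lm(vals[use] ~ arc[use]))[2]
}

# Greedy non-maximum suppression by score within a pixel radius.
nms_detections <- function(dets, radius = 6) {
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$score, dets$center_u, dets$center_v)
  keep <- logical(nrow(dets))
  for (i in ord) {
    close_kept <- keep &
      sqrt((dets$center_u - dets$center_u[i])^2 +
             (dets$center_v - dets$center_v[i])^2) < radius
    if (!any(close_kept)) keep[i] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

#' Detect leaf tips in an RGB image (baseline detector)
#'
#' Composition of [vegetation_mask()], [skeleton_endpoints()] and
#' [classify_tips()]; deterministic. This function fulfils the detector
#' plug-in contract consumed by the evaluation module: any external detector
#' returning the same columns is evaluable identically.
#'
#' @param image H x W x 3 array in \[0, 1\], or a `rendered_frame`.
#' @param gsd Ground sampling distance (mm/px); defaults to the frame's.
#' @param ... Tuning passed to [classify_tips()].
#' @return A detection tibble (see [classify_tips()]).
#' @export
detect_tips <- function(image, gsd = NULL, ...) {
  if (inherits(image, "rendered_frame")) {
    gsd <- gsd %||% image$gsd
    image <- image$rgb
  }
  mask <- vegetation_mask(image)
  if (!any(mask))
    return(tibble(center_u = double(), center_v = double(),
                  box_x = double(), box_y = double(),
                  box_w = double(), box_h = double(), score = double()))
  classify_tips(skeleton_endpoints(mask, prune = 2L), mask,
                gsd = gsd %||% NA, ...)
}

#' Write / read detections in the shared interchange dialect
#'
#' JSON paths get a COCO-style result list (`image`, `bbox = [x, y, w, h]`,
#' `score`); CSV paths a flat table.
#'
#' @param detections Detection tibble, optionally with an `image` column.
#' @param path Output `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  df <- as_tibble(detections)
  if (!"image" %in% names(df)) df$image <- NA_character_
  if (grepl("\\.json$", path)) {
    items <- lapply(seq_len(nrow(df)), function(i) list(
      image = df$image[i],
      bbox = c(df$box_x[i], df$box_y[i], df$box_w[i], df$box_h[i]),
      score = df$score[i], category_id = 1L))
    jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df[, c("image", "center_u", "center_v", "box_x",
                            "box_y", "box_w", "box_h", "score")],
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (grepl("\\.json$", path)) {
    items <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(items) == 0)
      return(tibble(image = character(), center_u = double(),
                    center_v = double(), box_x = double(), box_y = double(),
                    box_w = double(), box_h = double(), score = double()))
    bind_rows(lapply(items, function(it) {
      b <- unlist(it$bbox)
      tibble(image = it$image %||% NA_character_,
             center_u = b[1] + b[3] / 2, center_v = b[2] + b[4] / 2,
             box_x = b[1], box_y = b[2], box_w = b[3], box_h = b[4],
             score = it$score)
    }))
  } else {
    as_tibble(utils::read.csv(path))
  }
}
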
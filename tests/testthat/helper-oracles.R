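# Independent brute-force oracles, deliberately naive: every fast-path
# implementation in the package is checked against one of these on small
# inputs.

# exhaustive Otsu: try all 255 splits of an 8-bit histogram, maximise the
# between-class variance; foreground = level >= t, plateau ties resolved at
# the midpoint (the package's documented convention)
bf_otsu <- function(levels) {
  counts <- tabulate(levels + 1L, 256L)
  n <- sum(counts)
  sb <- rep(-Inf, 255)
  for (t in 1:255) {
    c0 <- which(0:255 < t)
    n0 <- sum(counts[c0])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[c0] * (c0 - 1)) / n0
    c1 <- which(0:255 >= t)
    mu1 <- sum(counts[c1] * (c1 - 1)) / n1
    sb[t] <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  }
  as.integer(floor(mean(which(sb >= max(sb) - 1e-12))))
}

# naive connected-component labelling by repeated breadth-first flooding
bf_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      vz <- (v - 1) %/% (d[1] * d[2])
      vy <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
      vx <- (v - 1) %% d[1]
      for (o in seq_len(nrow(offs))) {
        ux <- vx + offs[o, 1]; uy <- vy + offs[o, 2]; uz <- vz + offs[o, 3]
        if (ux < 0 || ux >= d[1] || uy < 0 || uy >= d[2] || uz < 0 || uz >= d[3]) next
        u <- 1 + ux + d[1] * (uy + d[2] * uz)
        if (mask[u] && lab[u] == 0L) {
          lab[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# boundary voxels: foreground with a 6-neighbour outside the mask
bf_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    vz <- (v - 1) %/% (d[1] * d[2])
    vy <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
    vx <- (v - 1) %% d[1]
    nb <- rbind(c(vx - 1, vy, vz), c(vx + 1, vy, vz), c(vx, vy - 1, vz),
                c(vx, vy + 1, vz), c(vx, vy, vz - 1), c(vx, vy, vz + 1))
    for (o in seq_len(6)) {
      u <- nb[o, ]
      if (any(u < 0) || u[1] >= d[1] || u[2] >= d[2] || u[3] >= d[3] ||
          !mask[1 + u[1] + d[1] * (u[2] + d[2] * u[3])]) {
        out[v] <- TRUE
        break
      }
    }
  }
  out
}

# brute-force HD95 on binary masks: all pairwise boundary distances
bf_hd95 <- function(a, b, spacing = c(1, 1, 1), method = "max_directed") {
  pts <- function(m) {
    w <- which(bf_boundary(m), arr.ind = TRUE)
    sweep(w, 2L, spacing, "*")
  }
  pa <- pts(a)
  pb <- pts(b)
  D <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      D[i, j] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
  da <- apply(D, 1L, min)
  db <- apply(D, 2L, min)
  v <- if (method == "pooled") stats::quantile(c(da, db), 0.95, names = FALSE)
       else max(stats::quantile(da, 0.95, names = FALSE),
                stats::quantile(db, 0.95, names = FALSE))
  v / 1000
}

# brute-force ball morphology: offsets with |o| <= r, borders = background
bf_ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(-ceiling(r):ceiling(r), -ceiling(r):ceiling(r),
                             -ceiling(r):ceiling(r)))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

bf_dilate <- function(mask, r) {
  d <- dim(mask)
  offs <- bf_ball_offsets(r)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    vz <- (v - 1) %/% (d[1] * d[2])
    vy <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
    vx <- (v - 1) %% d[1]
    for (o in seq_len(nrow(offs))) {
      u <- c(vx, vy, vz) + offs[o, ]
      if (any(u < 0) || u[1] >= d[1] || u[2] >= d[2] || u[3] >= d[3]) next
      out[1 + u[1] + d[1] * (u[2] + d[2] * u[3])] <- TRUE
    }
  }
  out
}

# erosion border convention: offsets falling outside the volume count as
# foreground (the package's documented field-of-view rule)
bf_erode <- function(mask, r) {
  d <- dim(mask)
  offs <- bf_ball_offsets(r)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    vz <- (v - 1) %/% (d[1] * d[2])
    vy <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
    vx <- (v - 1) %% d[1]
    keep <- TRUE
    for (o in seq_len(nrow(offs))) {
      u <- c(vx, vy, vz) + offs[o, ]
      if (any(u < 0) || u[1] >= d[1] || u[2] >= d[2] || u[3] >= d[3]) next
      if (!mask[1 + u[1] + d[1] * (u[2] + d[2] * u[3])]) {
        keep <- FALSE
        break
      }
    }
    if (keep) out[v] <- TRUE
  }
  out
}

# small shared fixtures
tiny_config <- function() {
  dbahnet_config(C = 4L, heads = c(1L, 2L, 2L, 4L), E = c(4L, 4L, 2L),
                 depths = c(1L, 1L, 1L))
}

overfit_config <- function() {
  dbahnet_config(C = 8L, heads = c(1L, 2L, 4L, 8L), E = c(4L, 4L, 2L))
}

# cortical thickness 8 voxels: comfortably above the 2*K_o + 1 = 7 the
# endosteal opening needs, as in real shaft scans; the fibula cross-section
# dominates any in-plane trabecular island so the per-slice rule targets it
small_phantom <- function(seed = 1L, noise_sigma = 0.05, ...) {
  generate_phantom(phantom_params(shape = c(64L, 64L, 24L), outer_radius = 17,
                                  inner_radius = 9, fibula_radius = 9,
                                  fibula_offset = c(29, 0), holder_width = 4L,
                                  noise_sigma = noise_sigma, seed = seed, ...))
}

crop_labels_to_bbox <- function(labels, bbox) {
  label_map(labels$voxels[bbox["lo", 1]:bbox["hi", 1],
                          bbox["lo", 2]:bbox["hi", 2],
                          bbox["lo", 3]:bbox["hi", 3], drop = FALSE],
            labels$spacing)
}
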
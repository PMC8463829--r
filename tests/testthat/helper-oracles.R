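# Independent oracles, kept deliberately separate from the implementation.

# Exact voxel-intersection (Siddon-style) WET: walk the ray from the grid
# boundary to the point, accumulating rsp * intersection length per voxel.
siddon_wet <- function(rsp, p, direction) {
  direction <- direction / sqrt(sum(direction^2))
  d <- dim(rsp$values)
  lo <- rsp$origin - rsp$spacing / 2
  hi <- rsp$origin + (d - 1) * rsp$spacing + rsp$spacing / 2
  # entry parameter going upstream: q(s) = p - s*direction, s in [0, smax]
  smax <- Inf
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-12) next
    bound <- if (direction[k] > 0) lo[k] else hi[k]
    smax <- min(smax, (p[k] - bound) / direction[k])
  }
  smax <- max(smax, 0)
  # collect all voxel-plane crossings along the segment
  ss <- c(0, smax)
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-12) next
    planes <- lo[k] + (0:d[k]) * rsp$spacing[k]
    sk <- (p[k] - planes) / direction[k]
    ss <- c(ss, sk[sk > 0 & sk < smax])
  }
  ss <- sort(unique(ss))
  wet <- 0
  for (i in seq_len(length(ss) - 1)) {
    smid <- (ss[i] + ss[i + 1]) / 2
    q <- p - smid * direction
    idx <- round((q - rsp$origin) / rsp$spacing) + 1
    idx <- pmin(pmax(idx, 1), d)
    wet <- wet + rsp$values[idx[1], idx[2], idx[3]] * (ss[i + 1] - ss[i])
  }
  wet
}

# direct transcription of the DVH-bandwidth formula
bandwidth_oracle <- function(nominal, vals) {
  N <- length(vals)
  2 * sqrt(sum((vals - nominal)^2) / (N - 1)) / nominal * 100
}

# brute-force counting DVH at given edges
dvh_count_oracle <- function(dose, edges) {
  vapply(edges, function(e) 100 * mean(dose >= e - 1e-12), numeric(1))
}

# plain transcription of the penalty objective
objective_oracle <- function(doses, spec, share = 1) {
  total <- 0
  for (t in spec$terms) {
    d <- doses[[t$structure]]
    ref <- t$dose * share
    pen <- if (t$type == "min") pmax(0, ref - d)^2
    else if (t$type == "max") pmax(0, d - ref)^2
    else (d - ref)^2
    total <- total + t$weight * mean(pen)
  }
  total
}
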
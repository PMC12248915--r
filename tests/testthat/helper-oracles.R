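# Brute-force reference implementations used to cross-check the package's
# optimised paths. Deliberately written as plain loops over definitions.

oracle_glrlm <- function(levels, ngray) {
  d <- dim(levels)
  maxlen <- max(d)
  out <- matrix(0L, ngray, maxlen)
  dirs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      dirs[[length(dirs) + 1]] <- c(dx, dy, dz)
  }
  inside <- function(v) all(v >= 1) && all(v <= d)
  for (dir in dirs) {
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      v <- c(x, y, z)
      lv <- levels[x, y, z]
      if (lv <= 0) next
      prev <- v - dir
      if (inside(prev) && levels[prev[1], prev[2], prev[3]] == lv) next
      len <- 1
      nxt <- v + dir
      while (inside(nxt) && levels[nxt[1], nxt[2], nxt[3]] == lv) {
        len <- len + 1
        nxt <- nxt + dir
      }
      out[lv, len] <- out[lv, len] + 1L
    }
  }
  out
}

oracle_glszm <- function(levels, ngray) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  idx <- which(levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v0 <- idx[r, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    lv <- levels[v0[1], v0[2], v0[3]]
    queue <- list(v0)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        t <- v + c(dx, dy, dz)
        if (any(t < 1) || any(t > d)) next
        if (!seen[t[1], t[2], t[3]] && levels[t[1], t[2], t[3]] == lv) {
          seen[t[1], t[2], t[3]] <- TRUE
          queue[[length(queue) + 1]] <- t
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  maxz <- max(1, vapply(zones, `[`, 0, 2))
  out <- matrix(0L, ngray, maxz)
  for (z in zones) out[z[1], z[2]] <- out[z[1], z[2]] + 1L
  out
}

oracle_gldm <- function(levels, ngray) {
  d <- dim(levels)
  out <- matrix(0L, ngray, 27)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    lv <- levels[x, y, z]
    if (lv <= 0) next
    dep <- 1
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      t <- c(x + dx, y + dy, z + dz)
      if (any(t < 1) || any(t > d)) next
      if (levels[t[1], t[2], t[3]] == lv) dep <- dep + 1
    }
    out[lv, dep] <- out[lv, dep] + 1L
  }
  out
}

# Direct elementwise summation of the scalar texture formulas.
oracle_texture_scalars <- function(P, n_voxels, kind, n_directions = 13) {
  Ns <- sum(P)
  nr <- nrow(P)
  nc <- ncol(P)
  acc <- function(f) {
    s <- 0
    for (i in 1:nr) for (j in 1:nc) if (P[i, j] > 0) s <- s + f(i, j, P[i, j])
    s
  }
  pg <- numeric(nr)
  ps <- numeric(nc)
  for (i in 1:nr) for (j in 1:nc) {
    pg[i] <- pg[i] + P[i, j]
    ps[j] <- ps[j] + P[i, j]
  }
  mu_i <- acc(function(i, j, c) i * c / Ns)
  mu_j <- acc(function(i, j, c) j * c / Ns)
  vals <- c(
    SE = acc(function(i, j, c) c / j^2) / Ns,
    LE = acc(function(i, j, c) c * j^2) / Ns,
    GLN = sum(pg^2) / Ns,
    GLNN = sum(pg^2) / Ns^2,
    SN = sum(ps^2) / Ns,
    SNN = sum(ps^2) / Ns^2,
    PCT = if (kind == "GLRLM") Ns / (n_voxels * n_directions)
          else Ns / n_voxels,
    GLV = acc(function(i, j, c) c / Ns * (i - mu_i)^2),
    SV = acc(function(i, j, c) c / Ns * (j - mu_j)^2),
    ENT = -acc(function(i, j, c) c / Ns * log2(c / Ns)),
    LGLE = acc(function(i, j, c) c / i^2) / Ns,
    HGLE = acc(function(i, j, c) c * i^2) / Ns,
    SLGL = acc(function(i, j, c) c / (i^2 * j^2)) / Ns,
    SHGL = acc(function(i, j, c) c * i^2 / j^2) / Ns,
    LLGL = acc(function(i, j, c) c * j^2 / i^2) / Ns,
    LHGL = acc(function(i, j, c) c * i^2 * j^2) / Ns)
  vals
}

# Maps package feature names onto the oracle's generic keys.
oracle_keys <- function(kind) {
  if (kind == "GLDM")
    c(SmallDependenceEmphasis = "SE", LargeDependenceEmphasis = "LE",
      GrayLevelNonUniformity = "GLN", DependenceNonUniformity = "SN",
      DependenceNonUniformityNormalized = "SNN", GrayLevelVariance = "GLV",
      DependenceVariance = "SV", DependenceEntropy = "ENT",
      LowGrayLevelEmphasis = "LGLE", HighGrayLevelEmphasis = "HGLE",
      SmallDependenceLowGrayLevelEmphasis = "SLGL",
      SmallDependenceHighGrayLevelEmphasis = "SHGL",
      LargeDependenceLowGrayLevelEmphasis = "LLGL",
      LargeDependenceHighGrayLevelEmphasis = "LHGL")
  else if (kind == "GLRLM")
    c(ShortRunEmphasis = "SE", LongRunEmphasis = "LE",
      GrayLevelNonUniformity = "GLN",
      GrayLevelNonUniformityNormalized = "GLNN",
      RunLengthNonUniformity = "SN",
      RunLengthNonUniformityNormalized = "SNN", RunPercentage = "PCT",
      GrayLevelVariance = "GLV", RunVariance = "SV", RunEntropy = "ENT",
      LowGrayLevelRunEmphasis = "LGLE", HighGrayLevelRunEmphasis = "HGLE",
      ShortRunLowGrayLevelEmphasis = "SLGL",
      ShortRunHighGrayLevelEmphasis = "SHGL",
      LongRunLowGrayLevelEmphasis = "LLGL",
      LongRunHighGrayLevelEmphasis = "LHGL")
  else
    c(SmallAreaEmphasis = "SE", LargeAreaEmphasis = "LE",
      GrayLevelNonUniformity = "GLN",
      GrayLevelNonUniformityNormalized = "GLNN",
      SizeZoneNonUniformity = "SN",
      SizeZoneNonUniformityNormalized = "SNN", ZonePercentage = "PCT",
      GrayLevelVariance = "GLV", ZoneVariance = "SV", ZoneEntropy = "ENT",
      LowGrayLevelZoneEmphasis = "LGLE", HighGrayLevelZoneEmphasis = "HGLE",
      SmallAreaLowGrayLevelEmphasis = "SLGL",
      SmallAreaHighGrayLevelEmphasis = "SHGL",
      LargeAreaLowGrayLevelEmphasis = "LLGL",
      LargeAreaHighGrayLevelEmphasis = "LHGL")
}

# O(n^2) pairwise concordance enumeration.
oracle_harrell <- function(risk, time, event) {
  n <- length(risk)
  num <- 0
  den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Single-voxel dynamic series wrapped for the volume-level fitters.
voxel_series <- function(pyr, lac, acq) {
  n <- length(pyr)
  dynamic_series(array(pyr, c(1, 1, 1, n)), array(lac, c(1, 1, 1, n)),
                 acq, diag(4))
}

# Random censored survival data for concordance/Cox checks.
random_survival <- function(n, censor_frac = 0.3) {
  time <- rexp(n)
  event <- as.integer(runif(n) > censor_frac)
  risk <- rnorm(n)
  list(risk = risk, time = time, event = event)
}

# Small multi-patient clinical table with prescribed outcomes.
make_records <- function(times_pfs, events_pfs, times_os = times_pfs * 1.5,
                         events_os = events_pfs, age = NULL) {
  n <- length(times_pfs)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age = if (is.null(age)) round(seq(55, 85, length.out = n))
                   else age,
             psa = seq(2, 40, length.out = n),
             ldh = seq(150, 300, length.out = n),
             alp = seq(40, 120, length.out = n),
             pfs_months = times_pfs, pfs_event = events_pfs,
             os_months = times_os, os_event = events_os)
}
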
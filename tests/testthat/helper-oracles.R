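# Independent oracles used across the suite. These are deliberately written
# against textbook formulas (partial-wave series, closed forms, brute-force
# enumeration) and never share code with the implementation they check.

# spherical Bessel/Hankel functions (half-order cylindrical Bessel)
sbesselj <- function(n, x) besselJ(x, n + 0.5) * sqrt(pi / (2 * x))
sbessely <- function(n, x) besselY(x, n + 0.5) * sqrt(pi / (2 * x))
sphankel2 <- function(n, x) sbesselj(n, x) - 1i * sbessely(n, x)
d_sbesselj <- function(n, x) {
  if (n == 0) -sbesselj(1, x) else sbesselj(n - 1, x) - (n + 1) / x * sbesselj(n, x)
}
d_sphankel2 <- function(n, x) {
  if (n == 0) -sphankel2(1, x) else sphankel2(n - 1, x) - (n + 1) / x * sphankel2(n, x)
}

legendre_pn <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (m in 2:n) {
    p <- ((2 * m - 1) * x * pm1 - (m - 1) * pm2) / m
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

# total pressure around a rigid sphere of radius a, plane wave exp(-ikz)
# travelling towards +z, e^{+i w t} time convention (outgoing = h_n^(2))
rigid_sphere_total_field <- function(a, k, r, costh, nmax = 25) {
  tot <- 0 + 0i
  for (n in 0:nmax) {
    cn <- (2 * n + 1) * (-1i)^n
    tot <- tot + cn * (sbesselj(n, k * r) -
                         d_sbesselj(n, k * a) / d_sphankel2(n, k * a) *
                         sphankel2(n, k * r)) * legendre_pn(n, costh)
  }
  tot
}

# brute-force per-frequency mean/sd over a ragged matrix (n-1 denominator)
brute_force_column_summary <- function(mat) {
  t(apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
      n = length(v))
  }))
}

# printed audiogram table and its printed summary rows
table3_matrix <- function() {
  path <- system.file("extdata", "behavioural_thresholds.csv", package = "resonear")
  read_threshold_matrix(path)
}

table3_printed <- function() {
  path <- system.file("extdata", "behavioural_thresholds_printed_summary.csv",
                      package = "resonear")
  utils::read.csv(path, colClasses = c("numeric", "character", "character"))
}

# single-degree-of-freedom resonator magnitude
sdof_magnitude <- function(f, f0, q) {
  w <- f / f0
  1 / sqrt((1 - w^2)^2 + (w / q)^2)
}

# decimal places of a printed number string
printed_decimals <- function(s) {
  s <- trimws(s)
  if (!grepl("\\.", s)) 0L else nchar(sub(".*\\.", "", s))
}

# small watertight STL writers for geometry tests
write_ascii_stl_sphere <- function(path, radius_mm = 1, n = 24) {
  # icosphere-free: latitude/longitude triangulation
  th <- seq(0, pi, length.out = n + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
  pt <- function(t, p) radius_mm * c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  tris <- list()
  for (i in seq_len(n)) {
    for (j in seq_along(ph)) {
      jp <- if (j == length(ph)) 1L else j + 1L
      a <- pt(th[i], ph[j]); b <- pt(th[i + 1], ph[j])
      cc <- pt(th[i + 1], ph[jp]); d <- pt(th[i], ph[jp])
      if (i == 1) {
        tris[[length(tris) + 1L]] <- rbind(a, b, cc)       # north cap fan
      } else if (i == n) {
        tris[[length(tris) + 1L]] <- rbind(a, b, d)        # south cap fan
      } else {
        tris[[length(tris) + 1L]] <- rbind(a, b, cc)
        tris[[length(tris) + 1L]] <- rbind(a, cc, d)
      }
    }
  }
  con <- file(path, "w")
  writeLines("solid sphere", con)
  for (tr in tris) {
    writeLines("facet normal 0 0 0", con)
    writeLines(" outer loop", con)
    for (r in 1:3) {
      writeLines(sprintf("  vertex %.9g %.9g %.9g", tr[r, 1], tr[r, 2], tr[r, 3]), con)
    }
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid sphere", con)
  close(con)
  path
}

write_ascii_stl_cube <- function(path, side_mm = 1, drop_last = FALSE) {
  s <- side_mm
  v <- rbind(c(0,0,0), c(s,0,0), c(s,s,0), c(0,s,0),
             c(0,0,s), c(s,0,s), c(s,s,s), c(0,s,s))
  f <- rbind(c(1,3,2), c(1,4,3), c(5,6,7), c(5,7,8),
             c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
             c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8))
  if (drop_last) f <- f[-nrow(f), , drop = FALSE]
  con <- file(path, "w")
  writeLines("solid cube", con)
  for (i in seq_len(nrow(f))) {
    writeLines("facet normal 0 0 0", con)
    writeLines(" outer loop", con)
    for (r in 1:3) {
      p <- v[f[i, r], ]
      writeLines(sprintf("  vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid cube", con)
  close(con)
  path
}
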
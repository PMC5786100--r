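# Independent oracles used to check the package's engines.  These
# implementations deliberately share no code path with the package: dense
# grids, quadrature and exhaustive scans instead of Monte Carlo and
# vectorized detection.

# --- dense-grid rasterization of a 2-D disk-union area -------------------
oracle_projected_area <- function(xy, radii, pitch = 0.01) {
  lo <- apply(xy - radii, 2, min)
  hi <- apply(xy + radii, 2, max)
  gx <- seq(lo[1] + pitch / 2, hi[1], by = pitch)
  gy <- seq(lo[2] + pitch / 2, hi[2], by = pitch)
  inside <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_len(nrow(xy))) {
    inside <- inside |
      outer((gx - xy[i, 1])^2, (gy - xy[i, 2])^2, `+`) <= radii[i]^2
  }
  sum(inside) * pitch^2
}

# --- classical deflection angle for a single LJ center -------------------
# chi(b, g) from the radial turning-point quadrature; energies in eV,
# lengths in angstrom, speeds in angstrom/ps, mass in amu.
.kB <- 8.617333262e-5
.CONV <- 1.03642697e-4

oracle_chi <- function(b, g, eps, sigma, mu) {
  U <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  E <- 0.5 * mu * g^2 * .CONV
  f <- function(r) 1 - (b / r)^2 - U(r) / E
  hi <- max(b, sigma) * 3 + 5
  rs <- seq(hi, 0.3, length.out = 4000)
  fv <- f(rs)
  i <- which(fv <= 0)[1]
  if (is.na(i)) {
    return(0)
  }
  r0 <- uniroot(f, c(rs[i], rs[i - 1]), tol = 1e-13)$root
  integrand <- function(t) {
    u0 <- 1 / r0
    u <- u0 * sin(t)
    ff <- 1 - b^2 * u^2 - U(1 / u) / E
    ff[ff < 0] <- 0
    out <- b * u0 * cos(t) / sqrt(ff)
    out[!is.finite(out)] <- 0
    out
  }
  val <- integrate(integrand, 0, pi / 2,
    rel.tol = 1e-8, subdivisions = 5000,
    stop.on.error = FALSE
  )$value
  pi - 2 * val
}

# --- 2-D (g, b) quadrature of the momentum-transfer collision integral --
oracle_omega_quadrature <- function(eps, sigma, mu, temperature,
                                    b_max = 20, n_gamma = 32) {
  Qg <- function(g) {
    f <- Vectorize(function(b) (1 - cos(oracle_chi(b, g, eps, sigma, mu))) * b)
    2 * pi * integrate(f, 1e-4, b_max,
      rel.tol = 1e-6, subdivisions = 400,
      stop.on.error = FALSE
    )$value
  }
  gam <- seq(0.05, 4, length.out = n_gamma)
  gs <- sqrt(2 * gam^2 * .kB * temperature / (mu * .CONV))
  Qv <- vapply(gs, Qg, 0)
  w <- gam^5 * exp(-gam^2)
  trap <- function(y) sum(diff(gam) * (head(y, -1) + tail(y, -1)) / 2)
  trap(w * Qv) / trap(w)
}

# --- exhaustive O(N^3) hydrogen-bond triple scan -------------------------
oracle_hbond_scan <- function(ensemble, conformer = 0, r_max = 3.5,
                              theta_max = 30, elements = c("N", "O"),
                              exclude_intra = TRUE) {
  x <- ensemble$coords[[conformer + 1]]
  el <- ensemble$atoms$element
  res <- ensemble$atoms$residue_index
  found <- list()
  for (h in which(el == "H")) {
    # covalent donor: nearest donor-element atom within 1.2 A
    best <- NA
    bestd <- Inf
    for (d in which(el %in% elements)) {
      dd <- sqrt(sum((x[h, ] - x[d, ])^2))
      if (dd < bestd) {
        bestd <- dd
        best <- d
      }
    }
    if (!is.finite(bestd) || bestd > 1.2) next
    d <- best
    for (a in which(el %in% elements)) {
      if (a == d) next
      if (exclude_intra && res[a] == res[d]) next
      rxy <- sqrt(sum((x[a, ] - x[d, ])^2))
      if (rxy >= r_max) next
      v1 <- x[h, ] - x[d, ]
      v2 <- x[a, ] - x[d, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < theta_max) {
        found[[length(found) + 1]] <- c(donor = d - 1, hydrogen = h - 1,
          acceptor = a - 1)
      }
    }
  }
  if (length(found) == 0) {
    return(matrix(numeric(0), 0, 3,
      dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))
    ))
  }
  do.call(rbind, found)
}

# --- brute-force rotation search for minimum RMSD ------------------------
oracle_min_rmsd <- function(a, b, n_start = 2000, seed = 99) {
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  f <- function(q) sqrt(mean(rowSums((b0 %*% t(rot_of(q)) - a0)^2)))
  set.seed(seed)
  qs <- matrix(rnorm(4 * n_start), ncol = 4)
  vals <- apply(qs, 1, f)
  best <- qs[which.min(vals), ]
  opt <- optim(best, f, control = list(maxit = 5000, reltol = 1e-14))
  opt$value
}

# --- small fixture builders ----------------------------------------------
make_test_pdb <- function(path, coords_list, elements = NULL) {
  n <- nrow(coords_list[[1]])
  if (is.null(elements)) elements <- rep(c("C", "O"), length.out = n)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(coords_list)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    x <- coords_list[[m]]
    for (i in seq_len(nrow(x))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s RES A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, paste0(elements[i], i), i, x[i, 1], x[i, 2], x[i, 3], elements[i]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
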
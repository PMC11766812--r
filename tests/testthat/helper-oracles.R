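# Independent numerical oracles, deliberately implemented with different
# algorithms than the code paths they check.

# winding-number point-in-polygon (the package uses ray casting)
pip_winding <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    ang <- 0
    on_boundary <- FALSE
    for (e in seq_len(n)) {
      j <- if (e == n) 1L else e + 1L
      ax <- v[e, 1] - x; ay <- v[e, 2] - y
      bx <- v[j, 1] - x; by <- v[j, 2] - y
      cr <- ax * by - ay * bx
      dt <- ax * bx + ay * by
      if (abs(cr) < 1e-9 * (abs(ax) + abs(bx) + 1) && dt <= 1e-12)
        on_boundary <- TRUE
      ang <- ang + atan2(cr, dt)
    }
    on_boundary || abs(ang) > pi
  }, logical(1))
}

# 4th-order central difference of a scalar function of one variable
fd_grad4 <- function(f, x, h) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}

# H field of a point dipole (moment m_vec at origin), SI
point_dipole_H <- function(m_vec, r_vec) {
  r2 <- sum(r_vec^2); r <- sqrt(r2)
  (3 * sum(m_vec * r_vec) * r_vec / r2 - m_vec) / (4 * pi * r^3)
}

default_assembly <- function() applicator_assembly()

# brute-force bead-level mean: expand each doublet event into two beads
# sharing the event total, then take the plain mean over beads
expanded_bead_mean <- function(singlet_fl4, doublet_fl4) {
  total <- sum(singlet_fl4) + sum(doublet_fl4)
  total / (length(singlet_fl4) + 2 * length(doublet_fl4))
}
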
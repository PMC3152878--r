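## Solvent-accessible surface area: Shrake-Rupley with a deterministic
## Fibonacci sphere.

## deterministic unit point set on the sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley: each atom's solvent sphere (vdW radius + probe) is sampled
#' with a deterministic Fibonacci point set; the accessible fraction times the
#' sphere area gives the atom's SASA.
#'
#' @param structure A [Structure-class].
#' @param probe_radius Solvent probe radius in A (default 1.4).
#' @param n_points Points per atom sphere (>= 92; default 960).
#' @return Numeric vector of per-atom areas (\eqn{\mathrm{\AA}^2}) in atom-table order;
#'   `sum()` gives the total SASA.
#' @export
computeSASA <- function(structure, probe_radius = 1.4, n_points = 960L) {
  stopifnot(n_points >= 92)
  a <- atomTable(structure)
  n <- nrow(a)
  if (!n) return(numeric())
  xyz <- coords(structure)
  rad <- vdwRadius(a$element) + probe_radius
  pts <- .fibonacci_sphere(n_points)
  out <- numeric(n)
  ## neighbour candidates via cell binning on the maximal reach
  reach <- max(rad) * 2
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / reach)
  cell_id <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(n), cell_id)
  key_of <- function(cx, cy, cz) paste(cx, cy, cz)
  neighbours_of <- function(i) {
    cx <- cell[i, 1]; cy <- cell[i, 2]; cz <- cell[i, 3]
    idx <- unlist(bins[key_of(rep(cx + (-1:1), each = 9),
                              rep(rep(cy + (-1:1), each = 3), 3),
                              rep(cz + (-1:1), 9))], use.names = FALSE)
    idx[idx != i]
  }
  for (i in seq_len(n)) {
    nb <- neighbours_of(i)
    if (length(nb)) {
      d2 <- colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2)
      nb <- nb[d2 < (rad[i] + rad[nb])^2]
    }
    if (!length(nb)) {
      out[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    xn <- xyz[nb, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(xn^2), "+") - 2 * p %*% t(xn)
    blocked <- d2 <= matrix(rad[nb]^2, n_points, length(nb), byrow = TRUE)
    out[i] <- 4 * pi * rad[i]^2 * sum(rowSums(blocked) == 0L) / n_points
  }
  out
}
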
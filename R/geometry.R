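## Internal 3D geometry helpers: torsion angles and internal-coordinate
## atom placement (NeRF construction) used to build idealised backbones.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Signed dihedral angle (degrees, IUPAC convention) of four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -rad2deg(atan2(y, x))
}

## Place atom D given positions A, B, C, the bond length C-D, the bond
## angle B-C-D (degrees) and the torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Idealised backbone internal coordinates (Engh-Huber-like averages).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5)

## Build an all-backbone (N, CA, C, O) + CB trace for a chain of length n
## following per-residue (phi, psi) vectors; omega fixed at 180 degrees.
## Returns a data.frame with resno, atom name, element and xyz.
build_backbone <- function(phi, psi, sequence = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  if (is.null(sequence)) sequence <- rep("A", n)
  stopifnot(length(sequence) == n)
  g <- BB_GEOM
  ## seed the first residue in a canonical frame
  N <- matrix(NA_real_, n, 3L)
  CA <- matrix(NA_real_, n, 3L)
  C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$n_ca, 0, 0)
  C[1L, ] <- CA[1L, ] + g$ca_c *
    c(cos(pi - deg2rad(g$ang_n_ca_c)), sin(pi - deg2rad(g$ang_n_ca_c)), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      ## N(i) from CA(i-1), C(i-1) and psi(i-1); CA(i) via omega; C(i) via phi(i)
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           g$c_n, g$ang_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, 180)
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ## carbonyl O: torsion relative to next N (or psi+180 for the terminus)
    o_tor <- if (i < n) {
      dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ]) + 180
    } else {
      psi[i] + 180
    }
    O <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, o_tor)
    atoms <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O)
    if (sequence[i] != "G") {
      ## CB branches off CA, roughly tetrahedral w.r.t. the N-CA-C plane
      atoms$CB <- place_atom(N[i, ], C[i, ], CA[i, ],
                             g$ca_cb, g$ang_n_ca_cb, 122.6)
    }
    elt <- substr(names(atoms), 1L, 1L)
    xyz <- do.call(rbind, atoms)
    rows[[i]] <- data.frame(
      resno = i, resid = AA_THREE[[sequence[i]]],
      elety = names(atoms), elesy = elt,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## phi/psi angles (degrees) from a coords table (as returned by
## read_structure / build_backbone); NA at chain ends or across breaks.
backbone_torsions <- function(atoms) {
  resnos <- sort(unique(atoms$resno))
  get <- function(rn, name) {
    r <- atoms[atoms$resno == rn & atoms$elety == name, c("x", "y", "z")]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r[1L, ])
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  ## consider residues consecutive only when numbering is adjacent and the
  ## peptide bond length is plausible (guards against chain breaks)
  for (k in seq_along(resnos)) {
    rn <- resnos[k]
    N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if ((rn - 1L) %in% resnos) {
      Cp <- get(rn - 1L, "C")
      if (!is.null(Cp) && vnorm(N - Cp) < 2.0)
        phi[k] <- dihedral_angle(Cp, N, CA, C)
    }
    if ((rn + 1L) %in% resnos) {
      Nn <- get(rn + 1L, "N")
      if (!is.null(Nn) && vnorm(Nn - C) < 2.0)
        psi[k] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}
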
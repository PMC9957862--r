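# Shared P2 (quadratic Lagrange) finite-element machinery on triangle meshes
# in the (r, z) half-plane. All volume integrals carry the axisymmetric
# weight r; the revolved (3D) measure is 2*pi times these integrals.

# 7-point degree-5 triangle quadrature (barycentric points, weights sum to 1/2
# on the unit reference triangle).
.tri_quad <- local({
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  pts <- rbind(c(1/3, 1/3),
               c(a1, b1), c(b1, a1), c(b1, b1),
               c(a2, b2), c(b2, a2), c(b2, b2))
  w <- c(9/40, rep(0.1323941527885062, 3), rep(0.1259391805448271, 3)) / 2
  list(xi = pts[, 1], eta = pts[, 2], w = w)
})

# P2 shape functions and reference gradients at one reference point.
.p2_shape <- function(xi, eta) {
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  N <- c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
         4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  dxi <- c(1 - 4 * l1, 4 * l2 - 1, 0, 4 * (l1 - l2), 4 * l3, -4 * l3)
  deta <- c(1 - 4 * l1, 0, 4 * l3 - 1, -4 * l2, 4 * l2, 4 * (l1 - l3))
  list(N = N, dxi = dxi, deta = deta)
}

# Global P2 dof structure: vertex dofs then edge-midpoint dofs, with a
# bandwidth-minimising permutation (dofs sorted by z level, then r).
.p2_dofs <- function(mesh) {
  t <- mesh$triangles
  v <- mesh$vertices
  eall <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  ekey <- paste(pmin(eall[, 1], eall[, 2]), pmax(eall[, 1], eall[, 2]))
  ukey <- unique(ekey)
  eid <- match(ekey, ukey)
  first <- match(ukey, ekey)
  edges <- eall[first, , drop = FALSE]
  nV <- nrow(v); nE <- nrow(t); nEd <- nrow(edges)
  ndof <- nV + nEd
  # element dof map (natural numbering): v1 v2 v3 m12 m23 m31
  dofmap <- cbind(t, nV + matrix(eid, nE, 3))
  coord <- rbind(v, (v[edges[, 1], , drop = FALSE] +
                     v[edges[, 2], , drop = FALSE]) / 2)
  perm <- order(coord[, 2], coord[, 1])
  newid <- integer(ndof); newid[perm] <- seq_len(ndof)
  list(ndof = ndof, nV = nV,
       dofmap = matrix(newid[dofmap], nE, 6),
       coord = coord[perm, , drop = FALSE],
       newid = newid,                 # natural -> banded numbering
       edge_key = ukey)               # "vmin vmax" -> edge index (nV offset)
}

# Midpoint dof (banded numbering) of a vertex pair.
.edge_dof <- function(dofs, v1, v2) {
  key <- paste(pmin(v1, v2), pmax(v1, v2))
  idx <- match(key, dofs$edge_key)
  if (anyNA(idx)) stop("internal: boundary edge not found in edge table")
  dofs$newid[dofs$nV + idx]
}

# Per-element P2 matrices (36 columns, pair (i,j) at column (j-1)*6+i):
#   Kw:  gradient stiffness with weight 1/r   (du/dr dv/dr + du/dz dv/dz) / r
#   Mw:  mass with weight 1/r                 u v / r
#   Kth: gradient stiffness with weight r     (du/dr dv/dr + du/dz dv/dz) r
#   M:   mass with weight r                   u v r
#   load: per-element load vector  integral(N_i r)  (6 columns)
# Kw/Mw serve the electromagnetic w = r*H_phi formulation (in which the coax
# TEM mode w = const is exactly representable); Kth/M with the standard
# axisymmetric weight r serve the thermal problem. Quadrature points are
# interior, so the 1/r weight stays finite on axis-touching elements; the
# axis dofs themselves carry an essential w = 0 condition.
.p2_element_matrices <- function(mesh, dofs) {
  t <- mesh$triangles; v <- mesh$vertices
  nE <- nrow(t)
  x1 <- v[t[, 1], 1]; y1 <- v[t[, 1], 2]
  x2 <- v[t[, 2], 1]; y2 <- v[t[, 2], 2]
  x3 <- v[t[, 3], 1]; y3 <- v[t[, 3], 2]
  j11 <- x2 - x1; j12 <- x3 - x1
  j21 <- y2 - y1; j22 <- y3 - y1
  det <- j11 * j22 - j12 * j21       # = 2 * area, positive for CCW
  i11 <- j22 / det; i12 <- -j12 / det
  i21 <- -j21 / det; i22 <- j11 / det

  Kw <- matrix(0, nE, 36); Mw <- matrix(0, nE, 36)
  Kth <- matrix(0, nE, 36); M <- matrix(0, nE, 36)
  load <- matrix(0, nE, 6)
  q <- .tri_quad
  for (k in seq_along(q$w)) {
    sh <- .p2_shape(q$xi[k], q$eta[k])
    rq <- x1 + j11 * q$xi[k] + j12 * q$eta[k]
    wdet <- q$w[k] * det
    Gr <- vector("list", 6); Gz <- vector("list", 6)
    for (i in 1:6) {
      Gr[[i]] <- sh$dxi[i] * i11 + sh$deta[i] * i21
      Gz[[i]] <- sh$dxi[i] * i12 + sh$deta[i] * i22
    }
    wr <- wdet * rq
    wir <- wdet / rq
    for (j in 1:6) {
      cj <- (j - 1L) * 6L
      for (i in 1:6) {
        gg <- Gr[[i]] * Gr[[j]] + Gz[[i]] * Gz[[j]]
        nn <- sh$N[i] * sh$N[j]
        Kw[, cj + i] <- Kw[, cj + i] + wir * gg
        Mw[, cj + i] <- Mw[, cj + i] + wir * nn
        Kth[, cj + i] <- Kth[, cj + i] + wr * gg
        M[, cj + i] <- M[, cj + i] + wr * nn
      }
      load[, j] <- load[, j] + wr * sh$N[j]
    }
  }
  ii <- dofs$dofmap[, rep(1:6, times = 6)]
  jj <- dofs$dofmap[, rep(1:6, each = 6)]
  list(Kw = Kw, Mw = Mw, Kth = Kth, M = M, load = load, ii = ii, jj = jj)
}

# P2 line matrices on tagged boundary edges: mass integral(N_i N_j w(r) ds)
# and load integral(f(r) N_i ds), with 3-point Gauss quadrature. Returns
# triplets over the 3 dofs (v1, v2, midpoint) of each edge.
.p2_edge_matrices <- function(mesh, dofs, edges_df, weight = function(r) r) {
  ne <- nrow(edges_df)
  v1 <- edges_df$v1; v2 <- edges_df$v2
  d1 <- dofs$newid[v1]; d2 <- dofs$newid[v2]
  dm <- .edge_dof(dofs, v1, v2)
  p1 <- mesh$vertices[v1, , drop = FALSE]
  p2 <- mesh$vertices[v2, , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  gt <- (c(-sqrt(3 / 5), 0, sqrt(3 / 5)) + 1) / 2   # on [0,1]
  gw <- c(5, 8, 5) / 18
  Kb <- matrix(0, ne, 9)
  for (k in 1:3) {
    tt <- gt[k]
    N <- c((1 - tt) * (1 - 2 * tt), tt * (2 * tt - 1), 4 * tt * (1 - tt))
    rq <- p1[, 1] + tt * (p2[, 1] - p1[, 1])
    wl <- gw[k] * len * weight(rq)
    for (j in 1:3) for (i in 1:3)
      Kb[, (j - 1L) * 3L + i] <- Kb[, (j - 1L) * 3L + i] + wl * N[i] * N[j]
  }
  dof3 <- cbind(d1, d2, dm)
  list(K = Kb,
       ii = dof3[, rep(1:3, times = 3), drop = FALSE],
       jj = dof3[, rep(1:3, each = 3), drop = FALSE],
       dof3 = dof3, len = len, p1 = p1, p2 = p2)
}

# Edge load vector integral(f(r) N_i ds): returns (dof, value) pairs.
.p2_edge_load <- function(mesh, dofs, edges_df, f) {
  ne <- nrow(edges_df)
  v1 <- edges_df$v1; v2 <- edges_df$v2
  p1 <- mesh$vertices[v1, , drop = FALSE]
  p2 <- mesh$vertices[v2, , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  gt <- (c(-sqrt(3 / 5), 0, sqrt(3 / 5)) + 1) / 2
  gw <- c(5, 8, 5) / 18
  L <- matrix(0, ne, 3)
  for (k in 1:3) {
    tt <- gt[k]
    N <- c((1 - tt) * (1 - 2 * tt), tt * (2 * tt - 1), 4 * tt * (1 - tt))
    rq <- p1[, 1] + tt * (p2[, 1] - p1[, 1])
    fv <- f(rq)
    for (i in 1:3) L[, i] <- L[, i] + gw[k] * len * fv * N[i]
  }
  dof3 <- cbind(dofs$newid[v1], dofs$newid[v2], .edge_dof(dofs, v1, v2))
  list(dof = as.vector(dof3), val = as.vector(L))
}

# Solve a complex sparse system given as triplets (already in a
# bandwidth-friendly numbering) with the LAPACK banded solver. 'fixed' dofs
# are eliminated (homogeneous Dirichlet).
.banded_solve_triplets <- function(ii, jj, vv, b, n, fixed = integer(0)) {
  if (length(fixed)) {
    keep <- rep(TRUE, n); keep[fixed] <- FALSE
    newn <- cumsum(keep)           # old -> new index (valid where keep)
    sel <- keep[ii] & keep[jj]
    ii <- newn[ii[sel]]; jj <- newn[jj[sel]]; vv <- vv[sel]
    b <- b[keep]
    nfree <- sum(keep)
  } else nfree <- n
  kl <- max(ii - jj); ku <- max(jj - ii)
  ldab <- 2L * kl + ku + 1L
  idx <- (jj - 1L) * ldab + (kl + ku + 1L + ii - jj)
  re <- rowsum(Re(vv), idx); im <- rowsum(Im(vv), idx)
  ab <- complex(as.double(ldab) * nfree)
  dim(ab) <- c(ldab, nfree)
  pos <- as.integer(rownames(re))
  ab[pos] <- complex(real = re[, 1], imaginary = im[, 1])
  x <- .Call(C_zgbsv, ab, as.integer(kl), as.integer(ku),
             as.complex(b))
  if (length(fixed)) {
    full <- complex(n)
    full[keep] <- x
    full
  } else x
}

# Evaluate a P2 field (values on dofs, banded numbering) and optionally its
# first derivatives at arbitrary points of a structured mesh.
# Returns NA outside the meshed domain.
.p2_eval <- function(mesh, dofs, vals, pts, derivatives = FALSE) {
  tri <- .mesh_locate(mesh, pts)
  ok <- !is.na(tri)
  n <- nrow(pts)
  out <- list(value = rep(NA_complex_, n), tri = tri)
  if (derivatives) {
    out$dr <- rep(NA_complex_, n); out$dz <- rep(NA_complex_, n)
  }
  if (!any(ok)) return(out)
  tr <- tri[ok]
  t <- mesh$triangles
  v <- mesh$vertices
  x1 <- v[t[tr, 1], 1]; y1 <- v[t[tr, 1], 2]
  x2 <- v[t[tr, 2], 1]; y2 <- v[t[tr, 2], 2]
  x3 <- v[t[tr, 3], 1]; y3 <- v[t[tr, 3], 2]
  j11 <- x2 - x1; j12 <- x3 - x1; j21 <- y2 - y1; j22 <- y3 - y1
  det <- j11 * j22 - j12 * j21
  dx <- pts[ok, 1] - x1; dy <- pts[ok, 2] - y1
  xi <- (j22 * dx - j12 * dy) / det
  eta <- (-j21 * dx + j11 * dy) / det
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  N <- cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
             4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  dm <- dofs$dofmap[tr, , drop = FALSE]
  uloc <- matrix(vals[dm], ncol = 6)
  out$value[ok] <- rowSums(N * uloc)
  if (derivatives) {
    dxi <- cbind(1 - 4 * l1, 4 * l2 - 1, 0 * l1, 4 * (l1 - l2), 4 * l3, -4 * l3)
    deta <- cbind(1 - 4 * l1, 0 * l1, 4 * l3 - 1, -4 * l2, 4 * l2, 4 * (l1 - l3))
    i11 <- j22 / det; i12 <- -j12 / det; i21 <- -j21 / det; i22 <- j11 / det
    out$dr[ok] <- rowSums((dxi * i11 + deta * i21) * uloc)
    out$dz[ok] <- rowSums((dxi * i12 + deta * i22) * uloc)
  }
  out
}

# Cached FEM structures for a mesh (dofs + element matrices), stored in the
# mesh's cache environment so repeated solves share the assembly geometry.
.fem_cache <- function(mesh) {
  if (is.null(mesh$cache)) stop("mesh has no cache environment; use generate_mesh()")
  if (is.null(mesh$cache$fem)) {
    dofs <- .p2_dofs(mesh)
    elem <- .p2_element_matrices(mesh, dofs)
    mesh$cache$fem <- list(dofs = dofs, elem = elem)
  }
  mesh$cache$fem
}
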
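#' @useDynLib cellhop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef sd splinefun rnorm runif dist approx
#' @importFrom utils head tail write.table read.csv packageVersion modifyList
#' @importFrom graphics hist
NULL

## Catalog of network cells, keyed by the topology label g (the number of
## faces of the polyhedral cell).  Dihedral angles are exact closed forms.
.cell_catalog <- list(
  `4`  = list(name = "tetrahedron",           n = 3, k = 3, theta = acos(1 / 3)),
  `6`  = list(name = "cube",                  n = 4, k = 3, theta = pi / 2),
  `8`  = list(name = "octahedron",            n = 3, k = 4, theta = acos(-1 / 3)),
  `12` = list(name = "dodecahedron",          n = 5, k = 3, theta = acos(-1 / sqrt(5))),
  `20` = list(name = "icosahedron",           n = 3, k = 5, theta = acos(-sqrt(5) / 3)),
  `32` = list(name = "truncated icosahedron", n = c(5L, 6L), k = 3,
              ## pentagon-hexagon and hexagon-hexagon dihedral angles
              theta = c(pent = acos(-sqrt((5 + 2 * sqrt(5)) / 15)),
                        hex  = acos(-sqrt(5) / 3)))
)

#' Labels of the network-cell catalog
#'
#' @return Integer vector of valid topology labels `g` (the face count of the
#'   polyhedral cell): 4, 6, 8, 12, 20, 32.
#' @export
cell_labels <- function() as.integer(names(.cell_catalog))

## Exact unit-edge vertex coordinates, centered at the origin.
.cell_vertices <- function(g_label) {
  phi <- (1 + sqrt(5)) / 2
  if (g_label == 4) {
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / (2 * sqrt(2))
  } else if (g_label == 6) {
    v <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / 2
  } else if (g_label == 8) {
    a <- 1 / sqrt(2)
    v <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
  } else if (g_label == 12) {
    s <- function(...) as.matrix(expand.grid(...))
    f1 <- s(c(-1, 1), c(-1, 1), c(-1, 1))
    f2 <- cbind(0, s(c(-1 / phi, 1 / phi), c(-phi, phi)))
    f3 <- f2[, c(2, 3, 1)]
    f4 <- f2[, c(3, 1, 2)]
    v <- rbind(f1, f2, f3, f4) * (phi / 2)  # edge length 2/phi -> scale to 1
  } else if (g_label == 20) {
    f <- as.matrix(expand.grid(c(-1, 1), c(-phi, phi)))
    f2 <- cbind(0, f)
    v <- rbind(f2, f2[, c(2, 3, 1)], f2[, c(3, 1, 2)]) / 2  # edge 2 -> 1
  } else if (g_label == 32) {
    ico <- .cell_vertices(20) * 3  # icosahedron with edge length 3
    ed <- .edges_by_distance(ico)
    v <- NULL
    for (r in seq_len(nrow(ed))) {
      a <- ico[ed[r, 1], ]; b <- ico[ed[r, 2], ]
      v <- rbind(v, a + (b - a) / 3, a + 2 * (b - a) / 3)
    }
  } else {
    stop("unknown g label")
  }
  dimnames(v) <- NULL
  v
}

## Edge list: all vertex pairs at the minimal pairwise distance (= edge length).
.edges_by_distance <- function(v, tol = 1e-6) {
  d <- as.matrix(dist(v))
  dmin <- min(d[d > tol])
  idx <- which(d < dmin * (1 + tol) & d > tol, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  unname(idx)
}

## Faces of a convex polyhedron from its vertices: supporting planes found from
## vertex triples; face vertices ordered as a cycle around the face centroid.
.faces_from_vertices <- function(v, tol = 1e-8) {
  nv <- nrow(v)
  seen <- character(0)
  faces <- list()
  for (i in 1:(nv - 2)) for (j in (i + 1):(nv - 1)) for (k in (j + 1):nv) {
    nrm <- .cross3(v[j, ] - v[i, ], v[k, ] - v[i, ])
    ln <- sqrt(sum(nrm^2))
    if (ln < tol) next
    nrm <- nrm / ln
    d0 <- sum(nrm * v[i, ])
    if (d0 < 0) { nrm <- -nrm; d0 <- -d0 }       # outward (cell centered at origin)
    proj <- v %*% nrm
    if (any(proj > d0 + tol)) next               # not a supporting plane
    memb <- which(abs(proj - d0) < tol)
    key <- paste(sort(memb), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    faces[[length(faces) + 1L]] <- .order_cycle(v, memb, nrm)
  }
  faces
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

.order_cycle <- function(v, memb, nrm) {
  ctr <- colMeans(v[memb, , drop = FALSE])
  e1 <- v[memb[1], ] - ctr; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(nrm, e1)
  ang <- apply(v[memb, , drop = FALSE], 1, function(p)
    atan2(sum((p - ctr) * e2), sum((p - ctr) * e1)))
  memb[order(ang)]
}

#' Build a polyhedral network cell
#'
#' Constructs the polyhedral cell associated with a topology label `g` (the
#' number of faces): 4 tetrahedron, 6 cube, 8 octahedron, 12 dodecahedron,
#' 20 icosahedron, 32 truncated icosahedron.  Strands of the macromolecular
#' network form the edges (all of length `a_x`, the mesh size) and cross-links
#' sit at the vertices.  The cell is centered at the origin.
#'
#' @param g_label integer topology label; one of [cell_labels()].
#' @param a_x mesh size (the length unit); default 1.
#' @return An object of class `polyhedral_cell`: a list with `g_label`, `name`,
#'   `n` (polygon degree, per face class for the truncated icosahedron), `k`
#'   (vertex functionality), `theta` (dihedral angle(s), radians), `a_x`,
#'   `vertices` (V x 3 matrix), `edges` (E x 2 index matrix), `faces` (list of
#'   vertex-index cycles).
#' @examples
#' cube <- build_cell(6)
#' nrow(cube$vertices)  # 8
#' @export
build_cell <- function(g_label, a_x = 1) {
  key <- as.character(as.integer(g_label))
  if (!key %in% names(.cell_catalog))
    stop("unknown g label ", g_label, "; valid labels: ",
         paste(names(.cell_catalog), collapse = ", "))
  if (!is.numeric(a_x) || a_x <= 0) stop("a_x must be positive")
  info <- .cell_catalog[[key]]
  v <- .cell_vertices(as.integer(g_label)) * a_x
  edges <- .edges_by_distance(v)
  faces <- .faces_from_vertices(v, tol = 1e-8 * a_x)
  structure(list(g_label = as.integer(g_label), name = info$name,
                 n = info$n, k = info$k, theta = info$theta, a_x = a_x,
                 vertices = v, edges = edges, faces = faces),
            class = "polyhedral_cell")
}

#' @export
print.polyhedral_cell <- function(x, ...) {
  cat(sprintf("Network cell g = %d (%s): V = %d, E = %d, F = %d, a_x = %g\n",
              x$g_label, x$name, nrow(x$vertices), nrow(x$edges),
              length(x$faces), x$a_x))
  invisible(x)
}

#' Characteristic radii from the closed-form expressions
#'
#' Inradius, midradius and circumradius of a regular polyhedral cell with
#' face degree `n` and dihedral angle `theta`:
#' \deqn{r_{in} = \tfrac{a_x}{2}\cot(\pi/n)\tan(\theta/2)}
#' \deqn{r_{mid} = \tfrac{a_x}{2}\cot(\pi/n)\sec(\theta/2)}
#' \deqn{r_{out} = \tfrac{a_x}{2}\cot(\pi/n)\sqrt{\sec^2(\theta/2)+\tan^2(\pi/n)}}
#'
#' @param n polygon degree of the faces (n >= 3).
#' @param theta dihedral angle in radians, 0 < theta < pi.
#' @param a_x mesh size.
#' @return A list with `r_in`, `r_mid`, `r_out` (class `radii_triple`).
#' @export
radii_eq1 <- function(n, theta, a_x = 1) {
  if (n < 3) stop("n must be >= 3")
  if (theta <= 0 || theta >= pi) stop("theta must lie in (0, pi)")
  ct <- 1 / tan(pi / n)
  r_in <- 0.5 * ct * tan(theta / 2) * a_x
  r_mid <- 0.5 * ct / cos(theta / 2) * a_x
  r_out <- 0.5 * ct * sqrt(1 / cos(theta / 2)^2 + tan(pi / n)^2) * a_x
  structure(list(r_in = r_in, r_mid = r_mid, r_out = r_out),
            class = "radii_triple")
}

#' Characteristic radii measured from the cell geometry
#'
#' Independent geometric route: `r_in` is the minimum centroid-to-face-plane
#' distance, `r_mid` the minimum centroid-to-edge distance, `r_out` the maximum
#' centroid-to-vertex distance.  For Archimedean cells with two face classes
#' (g = 32) this route is authoritative; the closed forms apply per face class.
#'
#' @param cell a `polyhedral_cell`.
#' @return A `radii_triple` list with `r_in`, `r_mid`, `r_out`.
#' @export
radii_geometric <- function(cell) {
  stopifnot(inherits(cell, "polyhedral_cell"))
  v <- cell$vertices
  r_out <- max(sqrt(rowSums(v^2)))
  ## face-plane distances
  r_in <- min(vapply(cell$faces, function(f) {
    fv <- v[f, , drop = FALSE]
    nrm <- .cross3(fv[2, ] - fv[1, ], fv[3, ] - fv[1, ])
    ln <- sqrt(sum(nrm^2))
    if (ln < 1e-12 * cell$a_x^2) stop("degenerate face (collinear vertices)")
    abs(sum(nrm / ln * fv[1, ]))
  }, numeric(1)))
  ## edge (segment) distances from the origin; edges never pass the centroid
  r_mid <- min(apply(cell$edges, 1, function(e) {
    p <- v[e[1], ]; q <- v[e[2], ]
    t <- max(0, min(1, -sum(p * (q - p)) / sum((q - p)^2)))
    sqrt(sum((p + t * (q - p))^2))
  }))
  structure(list(r_in = r_in, r_mid = r_mid, r_out = r_out),
            class = "radii_triple")
}

#' @export
print.radii_triple <- function(x, ...) {
  cat(sprintf("r_in = %.10g, r_mid = %.10g, r_out = %.10g\n",
              x$r_in, x$r_mid, x$r_out))
  invisible(x)
}

#' Minimum-energy-path frame through a face
#'
#' The minimum-energy path (MEP) connects the free-energy minimum at the cell
#' center to the local minimum at a face center.  The frame holds the unit axis
#' from the origin through the face centroid, the distance `z_face` to the face
#' plane (equal to the inradius for Platonic cells) and the period
#' `2 * z_face` (the neighboring cell center is the mirror image through the
#' face plane).
#'
#' @param cell a `polyhedral_cell`.
#' @param face_index face number, 1-based.
#' @return A list of class `mep_frame` with `origin`, `axis`, `z_face`,
#'   `period`, `face_index`.
#' @export
mep_frame <- function(cell, face_index = 1L) {
  stopifnot(inherits(cell, "polyhedral_cell"))
  if (face_index < 1 || face_index > length(cell$faces))
    stop("face_index out of range 1..", length(cell$faces))
  fv <- cell$vertices[cell$faces[[face_index]], , drop = FALSE]
  ctr <- colMeans(fv)
  nrm <- .cross3(fv[2, ] - fv[1, ], fv[3, ] - fv[1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (sum(nrm * ctr) < 0) nrm <- -nrm
  z_face <- abs(sum(nrm * fv[1, ]))  # distance to the face plane
  structure(list(origin = c(0, 0, 0), axis = nrm, z_face = z_face,
                 period = 2 * z_face, face_index = as.integer(face_index)),
            class = "mep_frame")
}

## Reflection of points through the plane of face `face_index`.
.reflect_through_face <- function(cell, face_index, pts) {
  fv <- cell$vertices[cell$faces[[face_index]], , drop = FALSE]
  nrm <- .cross3(fv[2, ] - fv[1, ], fv[3, ] - fv[1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  d0 <- sum(nrm * fv[1, ])
  pts - 2 * (pts %*% nrm - as.numeric(d0)) %*% t(nrm)
}

#' Discretize a cell into a bead-spring Gaussian-chain network
#'
#' Each strand (edge) becomes a chain of `N` Gaussian springs with `N - 1`
#' interior beads; cross-links sit at the vertices.  Spring energy is
#' \eqn{(3/2) k_B T |\Delta r|^2 / b^2} per bond with Kuhn length `b`
#' satisfying \eqn{\sqrt{N} b = a_x}.  With `replicate_neighbors = TRUE` the
#' first shell of mirror-image cells (one per face) is appended so a particle
#' crossing the MEP sees a realistic environment; the image cells' outer
#' cross-links are marked pinned.
#'
#' @param cell a `polyhedral_cell`.
#' @param N beads (bonds) per strand, N >= 1.
#' @param b Kuhn length; default `cell$a_x / sqrt(N)`.
#' @param replicate_neighbors append first-shell mirror-image cells.
#' @return Object of class `bead_network`: `crosslinks` (M x 3), `pinned`
#'   (logical M), `strands` (S x 2 cross-link index pairs), `sites` (all bead
#'   plus cross-link coordinates), `site_fixed`, `springs` (bond site-index
#'   pairs), `strand_sites` (list of site-index paths), `N`, `b`, `a_x`, `cell`.
#' @export
to_bead_network <- function(cell, N = 4L, b = NULL,
                            replicate_neighbors = FALSE) {
  stopifnot(inherits(cell, "polyhedral_cell"))
  N <- as.integer(N)
  if (N < 1) stop("N must be >= 1")
  if (is.null(b)) b <- cell$a_x / sqrt(N)
  if (abs(sqrt(N) * b - cell$a_x) > 0.01 * cell$a_x)
    stop("inconsistent discretization: sqrt(N) * b must equal a_x within 1%")

  xl <- cell$vertices
  pinned <- rep(FALSE, nrow(xl))
  key <- function(p) paste(round(p / cell$a_x, 7), collapse = ",")
  xl_keys <- apply(xl, 1, key)
  strands <- cell$edges

  if (replicate_neighbors) {
    ekey <- function(i, j) paste(sort(c(xl_keys[i], xl_keys[j])), collapse = "|")
    strand_keys <- apply(strands, 1, function(e) ekey(e[1], e[2]))
    for (f in seq_along(cell$faces)) {
      img <- .reflect_through_face(cell, f, cell$vertices)
      idx_map <- integer(nrow(img))
      for (r in seq_len(nrow(img))) {
        k <- key(img[r, ])
        hit <- match(k, xl_keys)
        if (is.na(hit)) {
          xl <- rbind(xl, img[r, ])
          pinned <- c(pinned, TRUE)        # image-only cross-link: pinned
          xl_keys <- c(xl_keys, k)
          hit <- length(xl_keys)
        }
        idx_map[r] <- hit
      }
      for (r in seq_len(nrow(cell$edges))) {
        e <- c(idx_map[cell$edges[r, 1]], idx_map[cell$edges[r, 2]])
        k <- ekey(e[1], e[2])
        if (!k %in% strand_keys) {
          strands <- rbind(strands, e)
          strand_keys <- c(strand_keys, k)
        }
      }
    }
  }

  ## interior beads: sites = [cross-links, beads...]; springs chain them
  sites <- xl
  site_fixed <- pinned
  springs <- NULL
  strand_sites <- vector("list", nrow(strands))
  for (s in seq_len(nrow(strands))) {
    i <- strands[s, 1]; j <- strands[s, 2]
    path <- i
    if (N > 1) {
      ts <- seq_len(N - 1) / N
      for (t in ts) {
        sites <- rbind(sites, xl[i, ] + t * (xl[j, ] - xl[i, ]))
        site_fixed <- c(site_fixed, FALSE)
        path <- c(path, nrow(sites))
      }
    }
    path <- c(path, j)
    strand_sites[[s]] <- path
    springs <- rbind(springs, cbind(path[-length(path)], path[-1]))
  }
  dimnames(sites) <- NULL
  structure(list(crosslinks = xl, pinned = pinned, strands = unname(strands),
                 sites = sites, site_fixed = site_fixed,
                 springs = unname(springs), strand_sites = strand_sites,
                 N = N, b = b, a_x = cell$a_x, cell = cell),
            class = "bead_network")
}

#' @export
print.bead_network <- function(x, ...) {
  cat(sprintf(paste0("Bead-spring network (g = %d): %d cross-links ",
                     "(%d pinned), %d strands, N = %d, b = %.4g\n"),
              x$cell$g_label, nrow(x$crosslinks), sum(x$pinned),
              nrow(x$strands), x$N, x$b))
  invisible(x)
}
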
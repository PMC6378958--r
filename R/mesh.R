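# Triangulated surface meshes: construction, normals, edges, ASCII I/O.

#' Construct a surface mesh
#'
#' @param vertices n x 3 matrix, meters.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 unit vertex normals (computed from face
#'   geometry when omitted).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
  m$normals <- if (is.null(normals)) vertex_normals(m) else {
    nn <- as.matrix(normals)
    nn / sqrt(rowSums(nn^2))
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tabulate2(f[, k], fn[, 1], nrow(v))
    n[, 2] <- n[, 2] + tabulate2(f[, k], fn[, 2], nrow(v))
    n[, 3] <- n[, 3] + tabulate2(f[, k], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Undirected edge list of a mesh
#' @param mesh a `surface_mesh`.
#' @return 2-column matrix of unique vertex index pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected on a sphere; the workhorse synthetic
#' scalp/cortex geometry.
#'
#' @param subdiv number of 4-fold subdivisions (0 -> 12 vertices, 1 -> 42,
#'   2 -> 162, 3 -> 642, 4 -> 2562).
#' @param radius sphere radius (m); @param center 3-vector.
#' @return a `surface_mesh`.
#' @export
icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- unname(sweep(v * radius, 2, center, `+`))
  surface_mesh(v, f)
}

#' Write / read a mesh as an ASCII OFF file
#'
#' Standard OFF: header, vertex count / face count, vertex coordinates, then
#' faces as `3 i j k` with 0-based indices.
#' @param mesh a `surface_mesh`; @param path file path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(fc)
    sprintf("3 %d %d %d", fc[1], fc[2], fc[3])), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fcs <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    a <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    a[2:4] + 1L
  }))
  surface_mesh(vtx, fcs)
}
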
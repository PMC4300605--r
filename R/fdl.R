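#' Parameters for the force-directed layout
#'
#' The embedder is a spring model: edges attract their endpoints toward a
#' rest length (`spring_length`, canvas units) with stiffness
#' `spring_coefficient`; all node pairs repel with force
#' `repulsion_constant / d^2`; movable nodes feel a weak gravity pull toward
#' the current centroid to keep disconnected components on canvas. The seed
#' fully determines the initial placement of positionless nodes, so a run is
#' reproducible from `(layout, params)` alone.
#'
#' @param iterations Number of relaxation steps.
#' @param spring_length Edge rest length in canvas units.
#' @param spring_coefficient Spring stiffness per unit extension.
#' @param repulsion_constant Pairwise repulsion scale (set 0 to disable).
#' @param seed Integer seed for the initial placement of positionless nodes.
#' @param movable_gravity Centroid-attraction coefficient for movable nodes.
#' @return An `fdl_params` list.
#' @export
fdl_params <- function(iterations = 500, spring_length = 80,
                       spring_coefficient = 0.05, repulsion_constant = 5000,
                       seed = 42, movable_gravity = 0.001) {
  if (iterations < 1 || spring_length <= 0 || spring_coefficient <= 0 ||
      repulsion_constant < 0 || movable_gravity < 0) {
    stop_argument("fdl_params: iterations/spring_length/spring_coefficient must be positive; repulsion_constant and movable_gravity non-negative")
  }
  structure(
    list(iterations = as.integer(iterations), spring_length = spring_length,
         spring_coefficient = spring_coefficient,
         repulsion_constant = repulsion_constant, seed = as.integer(seed),
         movable_gravity = movable_gravity),
    class = "fdl_params"
  )
}

#' Run the force-directed layout
#'
#' Positions every reaction and metabolite node. Fixed nodes are pinned:
#' their coordinates are bit-identical between input and output. Movable
#' nodes start from their stored coordinates when present, otherwise from a
#' seeded uniform disc around the centroid of the positioned nodes, and relax
#' under spring attraction, pairwise repulsion and gravity for
#' `params$iterations` steps with a linearly cooling displacement cap. Info
#' nodes take no part in the force simulation; they are placed beside their
#' reaction at render time.
#'
#' Positions depend on the graph structure, the stored coordinates and the
#' seed — not on node id strings — so renaming ids (keeping row order) leaves
#' the result unchanged.
#'
#' @param layout A `metabolic_layout`.
#' @param params An [fdl_params()] object.
#' @return The layout with all reaction/metabolite nodes positioned.
#' @export
run_fdl <- function(layout, params = fdl_params()) {
  rx <- layout$reactions
  mb <- layout$metabolites
  nr <- nrow(rx)
  ids <- c(rx$id, mb$id)
  n <- length(ids)
  if (n == 0) return(layout)

  pos <- cbind(c(rx$x, mb$x), c(rx$y, mb$y))
  fixed <- c(rx$fixed, mb$fixed)
  movable <- !fixed

  missing <- is.na(pos[, 1]) | is.na(pos[, 2])
  anchored <- !missing
  center0 <- if (any(anchored)) colMeans(pos[anchored, , drop = FALSE]) else c(0, 0)
  if (any(missing)) {
    set.seed(params$seed)
    k <- sum(missing)
    disc_r <- params$spring_length * max(1, sqrt(n) / 2)
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- disc_r * sqrt(stats::runif(k))
    pos[missing, 1] <- center0[1] + rad * cos(ang)
    pos[missing, 2] <- center0[2] + rad * sin(ang)
  }

  if (any(movable)) {
    ei <- match(layout$edges$reaction_id, ids)
    mi <- match(layout$edges$metabolite_id, ids)
    ok <- !is.na(ei) & !is.na(mi)
    ei <- ei[ok]; mi <- mi[ok]
    L <- params$spring_length
    for (it in seq_len(params$iterations)) {
      disp <- matrix(0, n, 2)
      if (params$repulsion_constant > 0 && n > 1) {
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        d2 <- dx * dx + dy * dy
        d2[d2 < 1e-4] <- 1e-4
        diag(d2) <- Inf
        d3 <- d2 * sqrt(d2)
        disp[, 1] <- rowSums(params$repulsion_constant * dx / d3)
        disp[, 2] <- rowSums(params$repulsion_constant * dy / d3)
      }
      if (length(ei)) {
        ddx <- pos[mi, 1] - pos[ei, 1]
        ddy <- pos[mi, 2] - pos[ei, 2]
        d <- pmax(sqrt(ddx * ddx + ddy * ddy), 1e-3)
        f <- params$spring_coefficient * (d - L)
        fx <- f * ddx / d
        fy <- f * ddy / d
        sx <- rowsum(c(fx, -fx), c(ei, mi))
        sy <- rowsum(c(fy, -fy), c(ei, mi))
        idx <- as.integer(rownames(sx))
        disp[idx, 1] <- disp[idx, 1] + sx[, 1]
        disp[idx, 2] <- disp[idx, 2] + sy[, 1]
      }
      if (params$movable_gravity > 0) {
        ctr <- colMeans(pos)
        disp[, 1] <- disp[, 1] + params$movable_gravity * (ctr[1] - pos[, 1])
        disp[, 2] <- disp[, 2] + params$movable_gravity * (ctr[2] - pos[, 2])
      }
      cap <- L * (1 - (it - 1) / params$iterations) + 1e-3
      len <- sqrt(disp[, 1]^2 + disp[, 2]^2)
      scl <- ifelse(len > cap, cap / len, 1)
      pos[movable, 1] <- pos[movable, 1] + disp[movable, 1] * scl[movable]
      pos[movable, 2] <- pos[movable, 2] + disp[movable, 2] * scl[movable]
    }
  }

  if (nr) {
    layout$reactions$x <- pos[seq_len(nr), 1]
    layout$reactions$y <- pos[seq_len(nr), 2]
  }
  if (nrow(mb)) {
    layout$metabolites$x <- pos[nr + seq_len(nrow(mb)), 1]
    layout$metabolites$y <- pos[nr + seq_len(nrow(mb)), 2]
  }
  layout
}
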
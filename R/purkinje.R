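#' Generate a fractal Purkinje conduction tree
#'
#' Grows a binary fractal tree over the endocardial surface starting from the
#' His node, in the spirit of fractal-tree conduction-system generators. With
#' `side = "right_only"` (the default, modelling complete left bundle branch
#' block) the tree is restricted to the right-ventricular endocardium and no
#' terminal couples to the LV endocardium. Each branch endpoint is projected
#' onto the nearest endocardial mesh node; leaves of the final generation are
#' the Purkinje-myocardial junctions (PMJs).
#'
#' @param mesh a `biv_mesh`.
#' @param side `"right_only"` or `"both"`.
#' @param branch_length initial branch length (mm).
#' @param length_decay multiplicative length decay per generation.
#' @param branching_angle half-angle between sibling branches (degrees).
#' @param generations number of branching generations.
#' @param v_purkinje conduction velocity in the tree (mm/ms, default 3).
#' @param seed integer seed for the angular jitter.
#' @return object of class `purkinje_tree` with tree `nodes` (coordinates),
#'   `edges` (from, to, length), `root`, `terminals` (tree node ids) and
#'   `pmj` (coupled mesh node id per terminal).
#' @export
generate_purkinje_tree <- function(mesh, side = c("right_only", "both"),
                                   branch_length = 20, length_decay = 0.8,
                                   branching_angle = 30, generations = 6,
                                   v_purkinje = 3, seed = 1L) {
  side <- match.arg(side)
  stopifnot(inherits(mesh, "biv_mesh"))
  if (generations < 1) stop("growth parameters yield zero terminals", call. = FALSE)
  rv_nodes <- mesh$surfaces$rv_endo
  if (!length(rv_nodes)) stop("RV endocardial surface is empty", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # outward face normals averaged per endocardial node, used as the local
  # rotation axis when branching
  normal_for <- function(surface_nodes, tag) {
    faces <- mesh$boundary_faces[mesh$boundary_tag == tag, , drop = FALSE]
    nrm <- matrix(0, nrow = nrow(mesh$nodes), ncol = 3)
    for (b in seq_len(nrow(faces))) {
      tri <- faces[b, ]
      e1 <- mesh$nodes[tri[2], ] - mesh$nodes[tri[1], ]
      e2 <- mesh$nodes[tri[3], ] - mesh$nodes[tri[1], ]
      fn <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      for (v in tri) nrm[v, ] <- nrm[v, ] + fn
    }
    nrm
  }

  grow_side <- function(surface_nodes, normals, adjacency, his_node, first_dir) {
    env <- new.env()
    env$nodes <- list(mesh$nodes[his_node, ])
    env$edges <- list()
    env$terminals <- integer()
    env$pmj <- integer()
    env$mesh_of <- his_node

    rotate <- function(v, axis, ang) {
      axis <- axis / sqrt(sum(axis^2))
      v * cos(ang) +
        c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1]) * sin(ang) +
        axis * sum(axis * v) * (1 - cos(ang))
    }
    # one branch = a directed walk on the endocardial face graph: at each
    # step move to the neighbour best aligned with the branch direction,
    # never stepping straight back, until the branch length is consumed
    grow <- function(tip, tip_mesh, dir, len, gen) {
      walked <- 0
      came_from <- -1L
      cur <- tip_mesh
      cur_tree <- tip
      while (walked < len) {
        nb <- adjacency[[cur]]
        nb <- nb[nb != came_from]
        if (!length(nb)) break
        steps <- mesh$nodes[nb, , drop = FALSE] -
          matrix(mesh$nodes[cur, ], length(nb), 3, byrow = TRUE)
        sl <- sqrt(rowSums(steps^2))
        score <- (steps / sl) %*% dir
        pick <- which.max(score)
        nxt <- nb[pick]
        id <- length(env$nodes) + 1L
        env$nodes[[id]] <- mesh$nodes[nxt, ]
        env$mesh_of[id] <- nxt
        env$edges[[length(env$edges) + 1L]] <- c(cur_tree, id, sl[pick])
        walked <- walked + sl[pick]
        came_from <- cur
        cur <- nxt
        cur_tree <- id
      }
      if (gen >= generations || cur_tree == tip) {
        env$terminals <- c(env$terminals, cur_tree)
        env$pmj <- c(env$pmj, cur)
        return(invisible())
      }
      axis <- normals[cur, ]
      if (sum(axis^2) < 1e-12) axis <- c(0, 0, 1)
      for (sgn in c(-1, 1)) {
        jit <- stats::runif(1, -5, 5)
        ang <- (sgn * branching_angle + jit) * pi / 180
        grow(cur_tree, cur, rotate(dir, axis, ang), len * length_decay, gen + 1L)
      }
    }
    grow(1L, his_node, first_dir, branch_length, 1L)
    env
  }

  surface_adjacency <- function(tag) {
    faces <- mesh$boundary_faces[mesh$boundary_tag == tag, , drop = FALSE]
    ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
    ed <- unique(rbind(ed, ed[, 2:1]))
    split(ed[, 2], ed[, 1])
  }
  as_adj_list <- function(sp) {
    adj <- vector("list", nrow(mesh$nodes))
    idx <- as.integer(names(sp))
    for (i in seq_along(sp)) adj[[idx[i]]] <- as.integer(sp[[i]])
    adj
  }

  rv_normals <- normal_for(rv_nodes, "rv_endo")
  rv_adj <- as_adj_list(surface_adjacency("rv_endo"))
  # His node: RV-endocardial node at the top of the septum, near the base
  his_target <- mesh$base_center +
    mesh$septal_axis * (mesh$params$lv_endo_radius + mesh$params$lv_wall) +
    mesh$long_axis * (-5)
  his_rv <- nearest_node(mesh, his_target, subset = rv_nodes)
  # aim the right bundle at the RV free wall (moderator-band-like course) so
  # the fractal tree covers the free wall, not only the septal face
  fw_nodes <- rv_nodes[!mesh$node_is$lv_epi[rv_nodes]]
  fw_target <- if (length(fw_nodes)) colMeans(mesh$nodes[fw_nodes, , drop = FALSE])
               else mesh$apex
  dir0 <- fw_target - mesh$nodes[his_rv, ]
  dir0 <- dir0 / sqrt(sum(dir0^2))
  env_r <- grow_side(rv_nodes, rv_normals, rv_adj, his_rv, dir0)

  nodes <- do.call(rbind, env_r$nodes)
  edges <- do.call(rbind, env_r$edges)
  terminals <- env_r$terminals
  pmj <- env_r$pmj

  if (side == "both") {
    lv_nodes <- mesh$surfaces$lv_endo
    lv_normals <- normal_for(lv_nodes, "lv_endo")
    lv_adj <- as_adj_list(surface_adjacency("lv_endo"))
    his_lv <- nearest_node(mesh, his_target, subset = lv_nodes)
    dir0l <- mesh$apex - mesh$nodes[his_lv, ]
    dir0l <- dir0l / sqrt(sum(dir0l^2))
    env_l <- grow_side(lv_nodes, lv_normals, lv_adj, his_lv, dir0l)
    off <- nrow(nodes)
    nodes_l <- do.call(rbind, env_l$nodes)
    edges_l <- do.call(rbind, env_l$edges)
    edges_l[, 1:2] <- edges_l[, 1:2] + off
    # bridge from the common His root to the left subtree root
    bridge_len <- sqrt(sum((nodes_l[1, ] - nodes[1, ])^2))
    nodes <- rbind(nodes, nodes_l)
    edges <- rbind(edges, c(1, off + 1L, max(bridge_len, 1e-6)), edges_l)
    terminals <- c(terminals, env_l$terminals + off)
    pmj <- c(pmj, env_l$pmj)
  }

  if (!length(terminals)) stop("growth parameters yield zero terminals", call. = FALSE)
  structure(list(nodes = nodes,
                 edges = data.frame(from = as.integer(edges[, 1]),
                                    to = as.integer(edges[, 2]),
                                    length = edges[, 3]),
                 root = 1L,
                 terminals = terminals,
                 pmj = pmj,
                 v_purkinje = v_purkinje,
                 side = side,
                 seed = as.integer(seed)),
            class = "purkinje_tree")
}

#' Activation times along a Purkinje tree
#'
#' Activation starts at the His node (time 0) and propagates along the tree at
#' the tree conduction velocity, so every node's time is its root-path length
#' divided by the velocity.
#'
#' @param tree a `purkinje_tree`.
#' @return numeric vector of activation times (ms) per tree node, class
#'   `tree_activation`.
#' @export
activate_tree <- function(tree) {
  stopifnot(inherits(tree, "purkinje_tree"))
  if (tree$v_purkinje <= 0) stop("v_purkinje must be positive", call. = FALSE)
  times <- rep(NA_real_, nrow(tree$nodes))
  times[tree$root] <- 0
  # edges were appended parent-before-child; one ordered pass suffices,
  # but iterate defensively in case of reordering
  edges <- tree$edges
  repeat {
    t_new <- times[edges$from] + edges$length / tree$v_purkinje
    upd <- !is.na(t_new) & (is.na(times[edges$to]) | t_new < times[edges$to])
    if (!any(upd)) break
    times[edges$to[upd]] <- t_new[upd]
  }
  if (anyNA(times)) stop("tree has unreachable nodes (not a rooted tree)", call. = FALSE)
  structure(times, class = c("tree_activation", "numeric"))
}

#' Myocardial sources from Purkinje-myocardial junctions
#'
#' @param tree a `purkinje_tree`.
#' @param activation a `tree_activation` from [activate_tree()].
#' @return tibble with `node` (mesh node id) and `onset` (ms), one row per
#'   terminal.
#' @export
pmj_sources <- function(tree, activation) {
  if (!length(tree$terminals)) stop("tree has no terminals", call. = FALSE)
  tibble::tibble(node = tree$pmj, onset = as.numeric(activation[tree$terminals]))
}

#' @export
print.purkinje_tree <- function(x, ...) {
  cat("<purkinje_tree>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$terminals), "terminals, side =", x$side, "\n")
  invisible(x)
}
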
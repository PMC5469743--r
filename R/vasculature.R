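# Capillary lattice and sprouting angiogenesis.
#
# Vessels live on the simulation lattice: segments connect 4-neighbor node
# pairs. The pre-existing capillary bed is a regular grid of perfused
# lines; hypovascularization is modeled by random removal of intratumoral
# segments. Angiogenic sprouts perform a biased lattice random walk up the
# TAF gradient (softmax step probabilities with ECM drag), branch
# stochastically, and anastomose when a tip lands on an existing vessel,
# upon which the new path becomes perfused and can deliver species.

#' Angiogenesis parameters
#'
#' @param taf_threshold Minimum TAF at a segment endpoint to spawn a sprout.
#' @param beta Chemotactic bias strength (softmax weight on the TAF
#'   difference between neighbor and current node).
#' @param p_branch Per-step tip branching probability.
#' @param p_sprout Per-call probability that an eligible segment emits a tip.
#' @param step_h Tip steps per hour.
#' @param perfuse_on_anastomosis Whether a sprout path becomes perfused when
#'   its tip fuses with an existing vessel.
#' @param ecm_drag ECM drag coefficient in the step weights
#'   (`1 / (1 + ecm_drag * E)`).
#' @param max_age_h Tip age (h) after which an unfused tip is retired.
#' @param max_tips Cap on simultaneously active tips.
#' @export
angiogenesis_params <- function(taf_threshold = 0.3, beta = 30, p_branch = 0.03,
                                p_sprout = 0.01, step_h = 0.5,
                                perfuse_on_anastomosis = TRUE, ecm_drag = 1,
                                max_age_h = 150, max_tips = 40) {
  if (taf_threshold < 0 || taf_threshold > 1) stop("taf_threshold must be in [0,1]")
  if (p_branch < 0 || p_branch > 1) stop("p_branch must be in [0,1]")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(taf_threshold = taf_threshold, beta = beta,
                 p_branch = p_branch, p_sprout = p_sprout, step_h = step_h,
                 perfuse_on_anastomosis = perfuse_on_anastomosis,
                 ecm_drag = ecm_drag, max_age_h = max_age_h,
                 max_tips = max_tips),
            class = "angiogenesis_params")
}

# internal: canonical segment key (order-independent)
segment_key <- function(x1, y1, x2, y2) {
  swap <- (x2 < x1) | (x2 == x1 & y2 < y1)
  a1 <- ifelse(swap, x2, x1); b1 <- ifelse(swap, y2, y1)
  a2 <- ifelse(swap, x1, x2); b2 <- ifelse(swap, y1, y2)
  paste(a1, b1, a2, b2, sep = ",")
}

new_vessel_network <- function(segments, tips, grid) {
  # lineage maps each sprout id to the ids of its ancestor sprouts (so an
  # anastomosing tip can mark its whole trail fused across branches);
  # visited holds each active tip's own trail nodes (no self-fusion)
  structure(list(segments = segments, tips = tips, grid = grid,
                 lineage = list(), visited = list()), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network: %d segments (%d perfused), %d active tips>\n",
              nrow(x$segments), sum(x$segments$perfused), nrow(x$tips)))
  invisible(x)
}

empty_tips <- function() {
  data.frame(id = integer(), x = integer(), y = integer(), age_h = numeric())
}

#' Build the regular capillary lattice
#'
#' Horizontal and vertical perfused vessel lines every `spacing_nodes`
#' lattice nodes (starting at node 1).
#'
#' @param grid A [sim_grid()].
#' @param spacing_nodes Line spacing in nodes (>= 2, smaller than the domain).
#' @return A `vessel_network`.
#' @export
build_capillary_grid <- function(grid, spacing_nodes = 10) {
  if (spacing_nodes < 2) stop("build_capillary_grid: spacing_nodes must be >= 2")
  if (spacing_nodes >= min(grid$nx, grid$ny))
    stop("build_capillary_grid: spacing larger than the domain")
  xs <- seq(1, grid$nx, by = spacing_nodes)
  ys <- seq(1, grid$ny, by = spacing_nodes)
  segs <- list()
  for (y in ys) # horizontal lines
    segs[[length(segs) + 1]] <- data.frame(
      x1 = seq_len(grid$nx - 1), y1 = y, x2 = 2:grid$nx, y2 = y)
  for (x in xs) # vertical lines
    segs[[length(segs) + 1]] <- data.frame(
      x1 = x, y1 = seq_len(grid$ny - 1), x2 = x, y2 = 2:grid$ny)
  segments <- do.call(rbind, segs)
  segments$perfused <- TRUE
  segments$sprout_id <- 0L
  segments$engulf_checked <- FALSE
  segments$fused <- TRUE # capillaries always conduct when connected
  segments <- segments[!duplicated(segment_key(segments$x1, segments$y1,
                                               segments$x2, segments$y2)), ]
  rownames(segments) <- NULL
  new_vessel_network(segments, empty_tips(), grid)
}

#' Randomly remove capillary segments inside the lesion
#'
#' Each segment whose midpoint lies in the lesion support is removed with
#' probability `p_prune`; reproducible for a fixed seed. Models the
#' under-developed vasculature of the tumor.
#'
#' @param net A `vessel_network`.
#' @param lesion A [lesion_state()].
#' @param p_prune Removal probability in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @export
prune_intratumoral <- function(net, lesion, p_prune, rng_seed = 1) {
  if (p_prune < 0 || p_prune > 1) stop("prune_intratumoral: p_prune in [0,1]")
  mask <- tumor_mask(lesion)
  s <- net$segments
  mx <- floor((s$x1 + s$x2) / 2 + 0.5); my <- floor((s$y1 + s$y2) / 2 + 0.5)
  inside <- mask[cbind(my, mx)]
  keep <- withr::with_seed(rng_seed, {
    u <- stats::runif(nrow(s))
    !(inside & u < p_prune)
  })
  net$segments <- s[keep, ]
  if (!is.null(net$segments$engulf_checked))
    net$segments$engulf_checked <- net$segments$engulf_checked | inside[keep]
  rownames(net$segments) <- NULL
  net
}

#' Recompute capillary perfusion from connectivity to the host network
#'
#' A capillary segment can only carry blood if it is connected, through
#' surviving capillaries or anastomosed (perfused) neovessels, to the host
#' network outside the lesion. Capillary fragments isolated inside the
#' tumor by pruning lose perfusion; sprout segments keep their
#' anastomosis-derived state and can reconnect fragments.
#'
#' @param net A `vessel_network`.
#' @param lesion A [lesion_state()] defining the tumor support.
#' @export
mark_perfusion_connectivity <- function(net, lesion) {
  s <- net$segments
  if (nrow(s) == 0) return(net)
  grid <- net$grid
  if (is.null(s$fused)) s$fused <- s$sprout_id == 0L | s$perfused
  # conducting subgraph: capillaries plus anastomosed (fused) neovessels
  cand <- s$fused
  if (!any(cand)) return(net)
  id1 <- (s$x1 - 1L) * grid$ny + s$y1
  id2 <- (s$x2 - 1L) * grid$ny + s$y2
  g <- igraph::graph_from_edgelist(
    cbind(as.character(id1[cand]), as.character(id2[cand])), directed = FALSE)
  comp <- igraph::components(g)$membership
  outside <- !tumor_mask(lesion)
  vout <- outside[cbind(((as.integer(names(comp)) - 1L) %% grid$ny) + 1L,
                        ((as.integer(names(comp)) - 1L) %/% grid$ny) + 1L)]
  ok_comp <- unique(comp[vout])
  seg_ok <- comp[as.character(id1[cand])] %in% ok_comp
  s$perfused <- FALSE
  s$perfused[cand] <- seg_ok
  net$segments <- s
  net
}

# internal: collapse pre-existing capillaries newly engulfed by the growing
# lesion with probability p_prune (the tumor stays hypovascularized as it
# expands); angiogenic vessels are exempt. Each segment is tested once.
engulf_prune <- function(net, lesion, p_prune) {
  s <- net$segments
  if (is.null(s$engulf_checked)) s$engulf_checked <- FALSE
  mask <- tumor_mask(lesion)
  mx <- floor((s$x1 + s$x2) / 2 + 0.5); my <- floor((s$y1 + s$y2) / 2 + 0.5)
  cand <- which(s$sprout_id == 0L & !s$engulf_checked & mask[cbind(my, mx)])
  if (length(cand) > 0) {
    drop <- cand[stats::runif(length(cand)) < p_prune]
    s$engulf_checked[cand] <- TRUE
    if (length(drop) > 0) s <- s[-drop, ]
  }
  net$segments <- s
  rownames(net$segments) <- NULL
  net
}

#' Spawn angiogenic sprout tips
#'
#' Perfused segments with an endpoint where TAF meets the spawn threshold
#' emit at most one new tip per call each (with per-segment probability
#' `p_sprout`), up to the global tip cap.
#'
#' @param net A `vessel_network`.
#' @param T_field TAF field in `[0, 1]`.
#' @param p An [angiogenesis_params()].
#' @export
spawn_sprouts <- function(net, T_field, p) {
  s <- net$segments
  if (nrow(s) == 0 || nrow(net$tips) >= p$max_tips) return(net)
  elig <- s$perfused &
    (T_field[cbind(s$y1, s$x1)] >= p$taf_threshold |
     T_field[cbind(s$y2, s$x2)] >= p$taf_threshold)
  idx <- which(elig)
  if (length(idx) == 0) return(net)
  emit <- idx[stats::runif(length(idx)) < p$p_sprout]
  if (length(emit) == 0) return(net)
  room <- p$max_tips - nrow(net$tips)
  if (length(emit) > room) emit <- emit[seq_len(room)]
  next_id <- if (nrow(net$tips) > 0 || length(net$lineage) > 0)
    max(c(net$tips$id, as.integer(names(net$lineage)), 0L)) + 1L else 1L
  # tip starts at the endpoint with higher TAF
  t1 <- T_field[cbind(s$y1[emit], s$x1[emit])]
  t2 <- T_field[cbind(s$y2[emit], s$x2[emit])]
  sx <- ifelse(t1 >= t2, s$x1[emit], s$x2[emit])
  sy <- ifelse(t1 >= t2, s$y1[emit], s$y2[emit])
  ids <- next_id + seq_along(emit) - 1L
  net$tips <- rbind(net$tips,
                    data.frame(id = ids, x = as.integer(sx),
                               y = as.integer(sy), age_h = 0))
  for (j in seq_along(ids)) {
    net$lineage[[as.character(ids[j])]] <- ids[j]
    net$visited[[as.character(ids[j])]] <-
      (as.integer(sx[j]) - 1L) * net$grid$ny + as.integer(sy[j])
  }
  net
}

# internal: logical matrix of nodes covered by any segment (perfused or not)
covered_nodes <- function(net, perfused_only = FALSE) {
  m <- matrix(FALSE, net$grid$ny, net$grid$nx)
  s <- net$segments
  if (perfused_only) s <- s[s$perfused, ]
  if (nrow(s) > 0) {
    m[cbind(s$y1, s$x1)] <- TRUE
    m[cbind(s$y2, s$x2)] <- TRUE
  }
  m
}

#' Advance all sprout tips one step
#'
#' Each tip moves to one of its 4 lattice neighbors with probability
#' proportional to `exp(beta * (T_nb - T_here)) / (1 + ecm_drag * E_nb)`,
#' laying a new (initially unperfused) segment. Tips branch with
#' probability `p_branch`, retire at the domain edge or when over-age, and
#' anastomose when landing on any covered vessel node outside their own
#' trail, upon which the tip is removed and its whole trail marked fused;
#' fused neovessels become perfused once
#' [mark_perfusion_connectivity()] finds them connected to the host
#' network (set `perfuse_on_anastomosis = FALSE` to keep them inert).
#'
#' @param net A `vessel_network`.
#' @param T_field TAF field.
#' @param E ECM density field.
#' @param p An [angiogenesis_params()].
#' @param dt_h Time represented by this step (h), used for tip aging.
#' @export
sprout_step <- function(net, T_field, E, p, dt_h = 1 / max(p$step_h, 1e-9)) {
  if (nrow(net$tips) == 0) return(net)
  grid <- net$grid
  # anastomosis target: any node covered by the network at step start;
  # a tip never fuses with its own trail (tracked in net$visited)
  cov <- covered_nodes(net)
  # O(1) duplicate-segment lookup: edge (node, orientation); orientation
  # 1 = horizontal (to x+1), 2 = vertical (to y+1), anchored at the
  # lexicographically smaller endpoint
  edge_tab <- matrix(FALSE, grid$ny * grid$nx, 2)
  s <- net$segments
  if (nrow(s) > 0) {
    horiz <- s$y1 == s$y2
    ax <- pmin(s$x1, s$x2); ay <- pmin(s$y1, s$y2)
    edge_tab[cbind((ax - 1L) * grid$ny + ay, ifelse(horiz, 1L, 2L))] <- TRUE
  }
  # neighbor order fixed: E, N, W, S (x+1, y+1, x-1, y-1)
  dx <- c(1L, 0L, -1L, 0L); dy <- c(0L, 1L, 0L, -1L)
  keep <- rep(TRUE, nrow(net$tips))
  new_segments <- list(); new_tips <- list()
  perfuse_ids <- integer()
  for (k in seq_len(nrow(net$tips))) {
    tx <- net$tips$x[k]; ty <- net$tips$y[k]; tid <- net$tips$id[k]
    age <- net$tips$age_h[k] + dt_h
    net$tips$age_h[k] <- age
    if (age > p$max_age_h) { keep[k] <- FALSE; next }
    nbx <- tx + dx; nby <- ty + dy
    ok <- nbx >= 1 & nbx <= grid$nx & nby >= 1 & nby <= grid$ny
    if (!all(ok)) { keep[k] <- FALSE; next } # tip at domain edge: retired
    w <- exp(pmin(p$beta * (T_field[cbind(nby, nbx)] - T_field[ty, tx]), 50)) /
      (1 + p$ecm_drag * E[cbind(nby, nbx)])
    ch <- sample.int(4, 1, prob = w)
    nx2 <- nbx[ch]; ny2 <- nby[ch]
    pk <- as.character(tid)
    ax <- min(tx, nx2); ay <- min(ty, ny2)
    eidx <- c((ax - 1L) * grid$ny + ay, if (ty == ny2) 1L else 2L)
    if (!edge_tab[eidx[1], eidx[2]]) {
      new_segments[[length(new_segments) + 1]] <-
        data.frame(x1 = tx, y1 = ty, x2 = nx2, y2 = ny2,
                   perfused = FALSE, sprout_id = tid, engulf_checked = TRUE,
                   fused = FALSE)
      edge_tab[eidx[1], eidx[2]] <- TRUE
    }
    nid <- (nx2 - 1L) * grid$ny + ny2
    net$visited[[pk]] <- c(net$visited[[pk]], nid)
    # fusion requires a minimum sprout length, so freshly spawned tips do
    # not instantly re-fuse with their parent vessel
    if (cov[ny2, nx2] && length(net$visited[[pk]]) > 5 &&
        !(nid %in% net$visited[[pk]][-length(net$visited[[pk]])])) {
      keep[k] <- FALSE
      if (p$perfuse_on_anastomosis) perfuse_ids <- c(perfuse_ids, tid)
    } else {
      net$tips$x[k] <- nx2; net$tips$y[k] <- ny2
      if (stats::runif(1) < p$p_branch &&
          nrow(net$tips) + length(new_tips) < p$max_tips) {
        bid <- max(c(net$tips$id, as.integer(names(net$lineage)), 0L)) + 1L +
          length(new_tips)
        new_tips[[length(new_tips) + 1]] <-
          data.frame(id = bid, x = tx, y = ty, age_h = age)
        net$lineage[[as.character(bid)]] <- c(net$lineage[[pk]], bid)
        net$visited[[as.character(bid)]] <- net$visited[[pk]]
      }
    }
  }
  if (length(new_segments) > 0)
    net$segments <- rbind(net$segments, do.call(rbind, new_segments))
  net$tips <- net$tips[keep, , drop = FALSE]
  if (length(new_tips) > 0) net$tips <- rbind(net$tips, do.call(rbind, new_tips))
  rownames(net$tips) <- NULL
  for (tid in unique(perfuse_ids)) {
    anc <- net$lineage[[as.character(tid)]]
    net$segments$fused[net$segments$sprout_id %in% anc] <- TRUE
  }
  # retired tips no longer need their trail record
  gone <- setdiff(names(net$visited), as.character(net$tips$id))
  net$visited[gone] <- NULL
  rownames(net$segments) <- NULL
  net
}

#' Perfused-vessel indicator field
#'
#' 1 at nodes covered by perfused segments, 0 elsewhere; unperfused sprouts
#' contribute nothing (they carry no blood).
#'
#' @param net A `vessel_network`.
#' @param grid A [sim_grid()] (defaults to the network's grid).
#' @export
vessel_indicator <- function(net, grid = net$grid) {
  m <- covered_nodes(net, perfused_only = TRUE)
  matrix(as.numeric(m), grid$ny, grid$nx)
}

#' Serialize a vessel network to a CSV edge list
#'
#' Columns `x1, y1, x2, y2, perfused` (lattice node indices).
#' @param net A `vessel_network`.
#' @param path Output file path.
#' @export
write_vessel_csv <- function(net, path) {
  utils::write.csv(net$segments[, c("x1", "y1", "x2", "y2", "perfused")],
                   path, row.names = FALSE)
  invisible(path)
}
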
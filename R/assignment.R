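# Frame-pair data association as a transportation/assignment problem.
# Detections in frame K are suppliers, detections in frame K+1 receivers;
# unmatched detections are routed through dummy birth/death nodes at a fixed
# penalty, which turns the rectangular transportation problem into a square
# linear assignment problem solved exactly.

# Large finite cost standing in for "no feasible link"; must dwarf any
# reachable total (costs are O(1) after gate normalization) while keeping the
# solver's dual arithmetic finite.
.INFEASIBLE <- 1e8

#' Tracking parameters
#'
#' Knobs of the frame-pair assignment tracker. Costs are normalized by
#' `gate_px`, so a spatial match at exactly the gate radius costs 1 and
#' `birth_death_cost` is scale-free: any value > 1 lets a within-gate
#' spatial match beat a birth+death pair when appearances agree.
#'
#' @param gate_px maximum plausible per-frame displacement in pixels; pairs
#'   farther apart are infeasible.
#' @param w_app weight of the appearance term (effectively 0 when detections
#'   carry no appearance vectors).
#' @param birth_death_cost cost of leaving one detection unmatched, in
#'   gated-distance units.
#' @param max_gap_frames how many consecutive missed frames a tracklet may
#'   coast (constant-velocity prediction) before being closed.
#' @param min_track_frames minimum frame span of a kept tracklet
#'   (default 13, about half a second at 25 fps).
#' @param min_track_disp_px minimum net displacement of a kept tracklet.
#' @return object of class `track_params`.
#' @export
track_params <- function(gate_px = 30, w_app = 1.0, birth_death_cost = 1.5,
                         max_gap_frames = 5, min_track_frames = 13,
                         min_track_disp_px = 10) {
  stopifnot(gate_px > 0, w_app >= 0, birth_death_cost > 0,
            max_gap_frames >= 0, min_track_frames >= 1,
            min_track_disp_px >= 0)
  structure(list(gate_px = gate_px, w_app = w_app,
                 birth_death_cost = birth_death_cost,
                 max_gap_frames = max_gap_frames,
                 min_track_frames = min_track_frames,
                 min_track_disp_px = min_track_disp_px),
            class = "track_params")
}

#' Pairwise link cost between two detections
#'
#' Dissimilarity of a frame-K detection and a frame-K+1 detection:
#' `euclidean(a, b) / gate_px + w_app * appdist(a, b)`, where `appdist` is
#' the Euclidean distance of the appearance vectors after scaling each
#' dimension by its range (so it lies in \[0, 1\]). Pairs farther apart than
#' `gate_px` are infeasible (`Inf`).
#'
#' @param a,b lists or one-row data.frames with `x_px`, `y_px` and optional
#'   numeric `appearance` vectors.
#' @param p a [track_params()].
#' @param app_scale optional per-dimension ranges used to normalize the
#'   appearance difference (defaults to 1 per dimension).
#' @return nonnegative cost, or `Inf` when the pair is outside the gate.
#' @export
pairwise_cost <- function(a, b, p = track_params(), app_scale = NULL) {
  d <- sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2)
  if (d > p$gate_px) return(Inf)
  cost <- d / p$gate_px
  aa <- a$appearance; ba <- b$appearance
  if (is.null(aa) != is.null(ba))
    stop("one detection has an appearance vector and the other does not")
  if (!is.null(aa)) {
    if (length(aa) != length(ba)) stop("appearance vector lengths differ")
    if (is.null(app_scale)) app_scale <- rep(1, length(aa))
    app_scale[app_scale <= 0] <- 1
    cost <- cost + p$w_app * sqrt(mean(((aa - ba) / app_scale)^2))
  }
  cost
}

# Exact square linear assignment (Jonker-Volgenant style shortest
# augmenting path with dual potentials, O(n^3)). Returns, for each row,
# its assigned column. Costs must be finite (use .INFEASIBLE, not Inf).
.lap_solve <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n)         # predecessor column on the alternating tree
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- cols[!used[cols]]
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      rows_used <- p[usedj]
      has_row <- rows_used > 0L
      u[rows_used[has_row]] <- u[rows_used[has_row]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign_of_row <- integer(n)
  assign_of_row[p[cols]] <- cols
  assign_of_row
}

# Build the gated cost matrix between two detection tables.
# Returns n x m matrix with .INFEASIBLE outside the gate.
.cost_matrix <- function(A, B, p, app_cols = character(0),
                         app_scale = NULL) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  dx <- outer(A$x_px, B$x_px, "-")
  dy <- outer(A$y_px, B$y_px, "-")
  d <- sqrt(dx * dx + dy * dy)
  C <- d / p$gate_px
  if (length(app_cols) && p$w_app > 0) {
    if (is.null(app_scale)) app_scale <- rep(1, length(app_cols))
    app_scale[app_scale <= 0] <- 1
    s2 <- matrix(0, n, m)
    for (k in seq_along(app_cols)) {
      da <- outer(A[[app_cols[k]]], B[[app_cols[k]]], "-") / app_scale[k]
      s2 <- s2 + da * da
    }
    C <- C + p$w_app * sqrt(s2 / length(app_cols))
  }
  C[d > p$gate_px] <- .INFEASIBLE
  C
}

#' Solve the frame-pair transportation problem
#'
#' Finds the global minimum-cost one-to-one partial matching between frame-K
#' detections (suppliers) and frame-K+1 detections (receivers); every
#' unmatched detection is charged `birth_death_cost`. Implemented as a square
#' linear assignment with dummy birth/death nodes and an exact
#' shortest-augmenting-path solver.
#'
#' @param K_dets,K1_dets data.frames of detections (columns `x_px`, `y_px`,
#'   optional appearance columns `a0..aK`); either may be empty.
#' @param p a [track_params()].
#' @param app_cols appearance column names shared by both tables.
#' @param app_scale per-dimension appearance ranges for normalization.
#' @param compute_margins logical; if `TRUE`, each match also gets its
#'   `margin`: the increase in total cost if that match were forbidden
#'   (computed by re-solving, so quadratic in instance size).
#' @return list of class `assignment_result` with `matches` (data.frame
#'   `i, j, cost, margin`), `births`, `deaths` (indices), `total_cost`.
#' @export
solve_frame_assignment <- function(K_dets, K1_dets, p = track_params(),
                                   app_cols = character(0), app_scale = NULL,
                                   compute_margins = FALSE) {
  n <- nrow(K_dets); m <- nrow(K1_dets)
  C <- .cost_matrix(K_dets, K1_dets, p, app_cols, app_scale)
  res <- .assign_with_dummies(C, n, m, p$birth_death_cost)
  if (compute_margins && nrow(res$matches)) {
    res$matches$margin <- vapply(seq_len(nrow(res$matches)), function(r) {
      C2 <- C
      C2[res$matches$i[r], res$matches$j[r]] <- .INFEASIBLE
      alt <- .assign_with_dummies(C2, n, m, p$birth_death_cost)
      alt$total_cost - res$total_cost
    }, numeric(1))
  }
  res
}

.assign_with_dummies <- function(C, n, m, bdc) {
  empty_matches <- data.frame(i = integer(0), j = integer(0),
                              cost = numeric(0), margin = numeric(0))
  if (n == 0L && m == 0L)
    return(structure(list(matches = empty_matches, births = integer(0),
                          deaths = integer(0), total_cost = 0),
                     class = "assignment_result"))
  S <- n + m
  M <- matrix(.INFEASIBLE, S, S)
  if (n && m) M[seq_len(n), seq_len(m)] <- C
  if (n) M[cbind(seq_len(n), m + seq_len(n))] <- bdc        # deaths
  if (m) M[cbind(n + seq_len(m), seq_len(m))] <- bdc        # births
  if (n && m) M[n + seq_len(m), m + seq_len(n)] <- 0        # dummy-dummy
  a <- .lap_solve(M)
  mi <- integer(0); mj <- integer(0)
  if (n) {
    real <- which(a[seq_len(n)] <= m)
    mi <- real; mj <- a[real]
  }
  if (length(mi) && any(C[cbind(mi, mj)] >= .INFEASIBLE))
    stop("internal error: infeasible pair matched")  # cannot happen: bdc route is cheaper
  ord <- order(mi, mj)
  mi <- mi[ord]; mj <- mj[ord]
  matches <- data.frame(i = mi, j = mj,
                        cost = if (length(mi)) C[cbind(mi, mj)] else numeric(0),
                        margin = rep(NA_real_, length(mi)))
  births <- setdiff(seq_len(m), mj)
  deaths <- setdiff(seq_len(n), mi)
  structure(list(matches = matches, births = births, deaths = deaths,
                 total_cost = sum(matches$cost) +
                   bdc * (length(births) + length(deaths))),
            class = "assignment_result")
}
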
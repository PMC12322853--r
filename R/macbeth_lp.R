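# MACBETH linear-programming machinery (internal).
#
# Variables, all non-negative:
#   v_1..v_n   raw item values
#   t_1..t_6   category thresholds
#   (M)        upper envelope of the values, minimax phase only
#   (s_c)      one slack per judgment, feasibility diagnosis only
#
# Constraint system (delta = 1):
#   t_1 >= delta;  t_{k+1} >= t_k + delta
#   judgment code k >= 1 on (i, j):  v_i - v_j >= t_k
#                        and, k <= 5: v_i - v_j <= t_{k+1} - delta
#   judgment code 0:                 v_i = v_j
#
# This is the standard ordinal-plus-semantic feasibility system used by
# MACBETH; the minimax objective plus a lexicographic clean-up pass makes
# the returned scale unique and deterministic.

MACBETH_DELTA <- 1
MACBETH_TOL <- 1e-7
# Box bound on every LP variable. The feasible optima of all solve phases
# are far below this (raw values and thresholds stay within ~6 * n_items);
# bounding the polytope sidesteps simplex pivot failures on unbounded rays.
MACBETH_BOX <- 1e4

# Build the constraint blocks shared by all solves.
# Returns list(A1, b1, A2, b2, A3, b3, nvar, slack_cols)
macbeth_constraints <- function(n_items, jd, slack = FALSE, minimax = FALSE) {
  nj <- nrow(jd)
  nvar <- n_items + 6L + as.integer(minimax) + if (slack) nj else 0L
  t_col <- function(k) n_items + k
  m_col <- n_items + 7L
  s_col <- function(c) n_items + 6L + as.integer(minimax) + c

  A1 <- NULL; b1 <- NULL   # <=
  A2 <- NULL; b2 <- NULL   # >=
  A3 <- NULL; b3 <- NULL   # ==
  row0 <- function() numeric(nvar)

  r <- row0(); r[t_col(1L)] <- 1
  A2 <- rbind(A2, r); b2 <- c(b2, MACBETH_DELTA)
  for (k in 1:5) {
    r <- row0(); r[t_col(k + 1L)] <- 1; r[t_col(k)] <- -1
    A2 <- rbind(A2, r); b2 <- c(b2, MACBETH_DELTA)
  }

  for (c in seq_len(nj)) {
    i <- jd$ii[c]; j <- jd$jj[c]; k <- jd$code[c]
    if (k == 0L) {
      if (slack) {
        r <- row0(); r[i] <- 1; r[j] <- -1; r[s_col(c)] <- -1
        A1 <- rbind(A1, r); b1 <- c(b1, 0)
        r <- row0(); r[j] <- 1; r[i] <- -1; r[s_col(c)] <- -1
        A1 <- rbind(A1, r); b1 <- c(b1, 0)
      } else {
        r <- row0(); r[i] <- 1; r[j] <- -1
        A3 <- rbind(A3, r); b3 <- c(b3, 0)
      }
    } else {
      r <- row0(); r[i] <- 1; r[j] <- -1; r[t_col(k)] <- -1
      if (slack) r[s_col(c)] <- 1
      A2 <- rbind(A2, r); b2 <- c(b2, 0)
      if (k <= 5L) {
        r <- row0(); r[i] <- 1; r[j] <- -1; r[t_col(k + 1L)] <- -1
        if (slack) r[s_col(c)] <- -1
        A1 <- rbind(A1, r); b1 <- c(b1, -MACBETH_DELTA)
      }
    }
  }

  if (minimax) {
    for (i in seq_len(n_items)) {
      r <- row0(); r[i] <- 1; r[m_col] <- -1
      A1 <- rbind(A1, r); b1 <- c(b1, 0)
    }
  }

  list(A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3,
       nvar = nvar,
       slack_cols = if (slack) vapply(seq_len(nj), s_col, 1L) else integer(0),
       m_col = if (minimax) m_col else NA_integer_)
}

solve_lp <- function(obj, cons, extraA1 = NULL, extrab1 = NULL) {
  A1 <- rbind(cons$A1, diag(cons$nvar))
  b1 <- c(cons$b1, rep(MACBETH_BOX, cons$nvar))
  if (!is.null(extraA1)) { A1 <- rbind(A1, extraA1); b1 <- c(b1, extrab1) }
  n_con <- length(b1) + length(cons$b2) + length(cons$b3)
  boot::simplex(a = obj, A1 = A1, b1 = b1,
                A2 = cons$A2, b2 = cons$b2,
                A3 = cons$A3, b3 = cons$b3,
                maxi = FALSE, n.iter = 50L * (cons$nvar + n_con))
}

# Convert the judgments of a judgment_matrix to integer-indexed form.
indexed_judgments <- function(x) {
  idx <- stats::setNames(seq_along(x$items), x$items)
  data.frame(ii = unname(idx[x$judgments$i]),
             jj = unname(idx[x$judgments$j]),
             code = x$judgments$code)
}

# Minimum total slack needed to satisfy all judgments; 0 iff consistent.
# Returns list(total, per_judgment).
min_slack <- function(n_items, jd) {
  if (nrow(jd) == 0L) return(list(total = 0, per_judgment = numeric(0)))
  cons <- macbeth_constraints(n_items, jd, slack = TRUE)
  obj <- numeric(cons$nvar)
  obj[cons$slack_cols] <- 1
  sol <- solve_lp(obj, cons)
  if (sol$solved != 1L) {
    # the slack system is always feasible; anything else is a solver failure
    mv_stop("LP solver failed on the slack feasibility system", "mv_lp_failure")
  }
  list(total = unname(sol$value),
       per_judgment = unname(sol$soln[cons$slack_cols]))
}

# Lexicographic minimax solve on a consistent system.
# Items tied by code-0 judgments are merged into one variable (equalities
# hold exactly by construction and the LP keeps only inequality rows,
# which the simplex handles robustly). Phase 1 minimises the largest raw
# value; subsequent phases fix the optimum (within tol) and minimise each
# value in item order, then the thresholds bottom-up, so the solution is
# unique and reproducible.
macbeth_solve <- function(n_items, jd) {
  # union-find over equality judgments
  parent <- seq_len(n_items)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (c in seq_len(nrow(jd))) {
    if (jd$code[c] == 0L) {
      ra <- find(jd$ii[c]); rb <- find(jd$jj[c])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n_items), find, 1L)
  classes <- sort(unique(root))
  cls <- match(root, classes)  # item -> class variable (ordered by first item)
  jd2 <- jd[jd$code > 0L, , drop = FALSE]
  if (nrow(jd2)) {
    jd2$ii <- cls[jd2$ii]
    jd2$jj <- cls[jd2$jj]
    if (any(jd2$ii == jd2$jj)) {
      stop_inconsistent("strict judgment between items tied by equality")
    }
  }
  sol <- macbeth_solve_classes(length(classes), jd2)
  list(values = sol$values[cls], thresholds = sol$thresholds)
}

macbeth_solve_classes <- function(n_items, jd) {
  cons <- macbeth_constraints(n_items, jd, minimax = TRUE)
  nvar <- cons$nvar
  fix_tol <- 1e-7

  obj <- numeric(nvar); obj[cons$m_col] <- 1
  sol <- solve_lp(obj, cons)
  if (sol$solved == -1L) {
    stop_inconsistent("judgment system is infeasible")
  }
  if (sol$solved != 1L) mv_stop("LP solver failed", "mv_lp_failure")

  extraA1 <- NULL; extrab1 <- NULL
  push_fix <- function(col, val) {
    r <- numeric(nvar); r[col] <- 1
    extraA1 <<- rbind(extraA1, r)
    extrab1 <<- c(extrab1, val + fix_tol)
  }
  push_fix(cons$m_col, unname(sol$value))

  for (col in c(seq_len(n_items), n_items + 1:6)) {
    obj <- numeric(nvar); obj[col] <- 1
    sol <- solve_lp(obj, cons, extraA1, extrab1)
    if (sol$solved != 1L) mv_stop("LP solver failed", "mv_lp_failure")
    push_fix(col, unname(sol$value))
  }

  x <- unname(sol$soln)
  list(values = x[seq_len(n_items)], thresholds = x[n_items + 1:6])
}
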
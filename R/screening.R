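# Safe screening and safe pattern pruning scores.
#
# All scores bound |X_j' alpha*| over a region known to contain the dual
# optimum.  A score strictly below lambda certifies beta*_j = 0 (screening),
# and the SPP score additionally certifies it for every descendant of j in
# the pattern tree (pruning), because its first term and its norm term are
# both monotone under support shrinkage.
#
# Columns are binary with support size s, so the centered norm is
# sqrt(s - s^2/n) and the plain norm is sqrt(s).

#' Safe screening score of a column
#'
#' `u_j = |X_j' alpha| + r * ||X_j - proj_1(X_j)||`; `u_j < lambda` implies
#' the pattern's optimal coefficient is zero (strict inequality; ties keep
#' the feature).
#'
#' @param support sorted instance indices where the pattern occurs.
#' @param ref a reference solution from [make_reference()] (uses fields
#'   `alpha` and `r`).
#' @param n number of instances.
#' @export
screening_score <- function(support, ref, n) {
  s <- length(support)
  abs(sum(ref$alpha[support])) + ref$r * sqrt(max(s - s^2 / n, 0))
}

#' Safe pattern pruning score of a subtree
#'
#' `v_j = max(sum of positive alpha on the support, -sum of negative alpha
#' on the support) + r * ||X_j||`; `v_j < lambda` eliminates the pattern and
#' its entire subtree.
#'
#' @inheritParams screening_score
#' @export
spp_score <- function(support, ref, n) {
  a <- ref$alpha[support]
  max(sum(a[a > 0]), -sum(a[a < 0]), 0) + ref$r * sqrt(length(support))
}

#' Geometry of two reference spheres
#'
#' Precomputes the quantities shared by all columns when screening with two
#' references: the center difference `delta`, the combination weight `t`,
#' the lens center `alpha'`, the reduced radius `r'`, and the cap thresholds
#' for the regions where one sphere's bound binds.  Degenerate cases
#' (coincident centers, nested or disjoint spheres, zero radii) set
#' `degenerate = TRUE`; scores then fall back to the minimum of the two
#' single-reference scores (still a valid bound).  Disjoint spheres indicate
#' an infeasible reference and raise a warning.
#'
#' @param R1,R2 reference solutions (centered dual vectors with radii).
#' @return list consumed by [multi_screening_score()].
#' @export
multi_ref_geometry <- function(R1, R2) {
  delta <- R1$alpha - R2$alpha
  d2 <- sum(delta^2)
  r1 <- R1$r; r2 <- R2$r
  geo <- list(delta = delta, d2 = d2, r1 = r1, r2 = r2, degenerate = TRUE)
  if (d2 < 1e-24 || r1 <= 0 || r2 <= 0) return(geo)
  d <- sqrt(d2)
  if (d > r1 + r2) {
    warning("reference spheres are disjoint; falling back to single-reference bounds",
            call. = FALSE)
    return(geo)
  }
  if (d <= abs(r1 - r2)) return(geo)  # one sphere inside the other
  t <- 0.5 * (1 + (r2^2 - r1^2) / d2)
  geo$t <- t
  geo$alpha_prime <- t * R1$alpha + (1 - t) * R2$alpha
  geo$r_prime <- sqrt(max(r2^2 - t^2 * d2, 0))
  geo$c1 <- (r2^2 - r1^2 - d2) / (2 * r1)
  geo$c2 <- (r2^2 - r1^2 + d2) / (2 * r2)
  geo$degenerate <- FALSE
  geo
}

#' Two-reference safe screening score
#'
#' Closed-form maximum of `|X_j' alpha|` over the intersection of the two
#' GAP spheres and the centering hyperplane, in O(n) per column: whichever
#' of the two spherical caps binds gives a single-reference-style bound, and
#' otherwise the maximum sits on the lens boundary with the reduced radius
#' `r'` and the norm of the column with both the constant direction and the
#' `delta` direction projected out.
#'
#' @param support sorted instance indices of the column.
#' @param R1,R2 reference solutions.
#' @param geo the output of [multi_ref_geometry()] for `(R1, R2)`.
#' @param n number of instances.
#' @export
multi_screening_score <- function(support, R1, R2, geo, n) {
  if (geo$degenerate) {
    return(min(screening_score(support, R1, n),
               screening_score(support, R2, n)))
  }
  s <- length(support)
  pc2 <- max(s - s^2 / n, 0)        # ||a - proj_1(a)||^2
  if (pc2 <= 0) return(0)           # constant column: a'alpha = 0 on H
  pc <- sqrt(pc2)
  a_d <- sum(geo$delta[support])    # a'delta
  a_1 <- sum(R1$alpha[support])
  a_2 <- sum(R2$alpha[support])
  a_p <- sum(geo$alpha_prime[support])
  orth <- sqrt(max(pc2 - a_d^2 / geo$d2, 0))
  one_sided <- function(sgn) {
    ratio <- sgn * a_d / pc
    if (ratio <= geo$c1) {
      sgn * a_1 + geo$r1 * pc
    } else if (ratio >= geo$c2) {
      sgn * a_2 + geo$r2 * pc
    } else {
      sgn * a_p + geo$r_prime * orth
    }
  }
  max(one_sided(1), one_sided(-1))
}

#' Two-reference pruning score
#'
#' The subtree bound with two references is the minimum of the two
#' single-reference SPP scores (the lens pruning bound has no closed form).
#'
#' @inheritParams multi_screening_score
#' @export
multi_spp_score <- function(support, R1, R2, n) {
  min(spp_score(support, R1, n), spp_score(support, R2, n))
}
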
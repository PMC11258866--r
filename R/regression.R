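## Design-matrix assembly from reference data, bounded weighted LASSO over a
## geometric lambda path (self-contained cyclic coordinate descent), the
## sparsity-walk selection of lambda_best, and training/validation statistics.

#' Assemble design matrices and observations from a reference dataset
#'
#' The forces block `M1` has one row per force component (3 per atom per
#' geometry) and one column per attempted force constant; entry `(i, j)` is
#' minus the derivative of term `j`'s duplicate-weighted summed basis
#' function with respect to that Cartesian coordinate, so that predicted
#' forces are `M1 %*% beta`. The torsion block `M2` has one row per scan
#' point of each rotatable dihedral type; each column holds the term's summed
#' basis values along the scan, centered by subtracting the scan average
#' (matching the no-intercept model: scan energies are likewise centered).
#' Terms whose internal coordinates do not move along a rigid scan give
#' exactly-zero centered columns, so torsion rows couple only to
#' rotatable-dihedral columns.
#'
#' @param model a `flex_model` template (force constants free)
#' @param dataset a `reference_dataset`
#' @param icset the `icoord_set` the model was built from (only needed when
#'   scan rows are present)
#' @param tags which geometry tags enter the force block
#' @param include_scans include the torsion-scan energy block
#' @param gradient `"analytic"` (closed-form internal-coordinate gradients,
#'   the default) or `"numeric"` (central differences; cross-validation)
#' @param h finite-difference step for the numeric route
#' @return list with `M` (rows = force components then scan points), `Y`,
#'   `part` (factor: `"forces"` / `"rot_dihedrals"`), `atom` (atom index per
#'   force row, NA for scan rows), `n_force_geoms`
#' @export
build_design <- function(model, dataset, icset = NULL,
                         tags = c("optimized", "hessian_displacement",
                                  "aimd_train"),
                         include_scans = TRUE,
                         gradient = c("analytic", "numeric"), h = 1e-5) {
  gradient <- match.arg(gradient)
  structure0 <- dataset$structure
  n <- n_atoms(structure0)
  p <- length(model$terms)
  sel <- vapply(dataset$geometries, function(g) g$tag %in% tags, logical(1L))
  geoms <- dataset$geometries[sel]
  n_g <- length(geoms)
  m1 <- matrix(0, 3L * n * n_g, p)
  y1 <- numeric(3L * n * n_g)
  atom_row <- rep(rep(seq_len(n), each = 3L), n_g)
  for (gi in seq_len(n_g)) {
    g <- structure0
    g$positions <- geoms[[gi]]$positions
    rows <- ((gi - 1L) * 3L * n + 1L):(gi * 3L * n)
    y1[rows] <- as.numeric(t(geoms[[gi]]$forces))
    for (j in seq_len(p)) {
      gr <- if (gradient == "analytic") {
        eval_term(model$terms[[j]], g, grad = TRUE)$grad
      } else {
        .numeric_term_grad(model$terms[[j]], g, h)
      }
      m1[rows, j] <- -as.numeric(t(gr))
    }
  }
  part <- rep("forces", length(y1))
  m2 <- NULL; y2 <- NULL
  if (include_scans && length(dataset$scans)) {
    ## columns: evaluate every rotatable-torsion term on the scan geometries;
    ## all other columns are exactly zero after centering
    rot_cols <- which(vapply(model$terms, function(tm) {
      tm$kind %in% c("torsion_cadt_mode", "torsion_addt_mode") &&
        identical(tm$classification, "rotatable")
    }, logical(1L)))
    for (s in dataset$scans) {
      scan_geoms <- .scan_geometries(s, icset, structure0)
      t_pts <- length(s$phi_deg)
      block <- matrix(0, t_pts, p)
      for (j in rot_cols) {
        vals <- vapply(scan_geoms, function(g)
          eval_term(model$terms[[j]], g)$g, numeric(1L))
        block[, j] <- vals - mean(vals)
      }
      m2 <- rbind(m2, block)
      y2 <- c(y2, s$energies - mean(s$energies))
      part <- c(part, rep("rot_dihedrals", t_pts))
    }
  }
  list(M = rbind(m1, m2), Y = c(y1, y2), part = factor(part),
       atom = c(atom_row, rep(NA_integer_, length(y2))),
       n_force_geoms = n_g)
}

.scan_geometries <- function(s, icset, structure0) {
  if (!is.null(s$geometries)) return(s$geometries)
  if (is.null(icset)) stop("icset needed to regenerate scan geometries")
  if (is.na(s$instance_row)) {
    ## CSV-sourced scan: regenerate for the seeded representative instance
    stop("scan has no geometries and no instance row; regenerate scans ",
         "through the pipeline before building the design")
  }
  scan <- generate_torsion_scan(icset, s$instance_row,
                                step_deg = diff(s$phi_deg[1:2]))
  scan$geometries
}

.numeric_term_grad <- function(term, geometry, h = 1e-5) {
  n <- n_atoms(geometry)
  gr <- matrix(0, n, 3L)
  for (a in seq_len(n)) for (x in 1:3) {
    gp <- geometry; gp$positions[a, x] <- gp$positions[a, x] + h
    gm <- geometry; gm$positions[a, x] <- gm$positions[a, x] - h
    gr[a, x] <- (eval_term(term, gp)$g - eval_term(term, gm)$g) / (2 * h)
  }
  gr
}

#' Assign box bounds for the force constants
#'
#' Lower bound zero for bond stretches, Urey-Bradley stretches, angle bends,
#' nonrotatable/hindered single-mode torsions, linear-dihedral modes, and
#' rotatable torsions with a single smart-selected mode; minus infinity for
#' multi-mode rotatable torsions and bond-bond cross terms. No upper bounds.
#' @param model a `flex_model`
#' @return list with numeric vectors `lb` and `ub`
#' @export
assign_bounds <- function(model) {
  ## count modes per rotatable dihedral type
  rot_modes <- table(vapply(model$terms, function(tm) {
    if (tm$kind %in% c("torsion_cadt_mode", "torsion_addt_mode") &&
        identical(tm$classification, "rotatable")) tm$type else NA_integer_
  }, integer(1L)), useNA = "no")
  lb <- vapply(model$terms, function(tm) {
    switch(tm$kind,
           bond_stretch = 0, ub_stretch = 0, angle_bend = 0,
           torsion_addt_linear_mode = 0,
           bond_bond_cross = -Inf,
           torsion_cadt_mode = ,
           torsion_addt_mode = {
             if (identical(tm$classification, "rotatable") &&
                 rot_modes[[as.character(tm$type)]] > 1L) -Inf else 0
           })
  }, numeric(1L))
  list(lb = lb, ub = rep(Inf, length(lb)))
}

#' Observation weights per training part
#'
#' Within each training part (force components; rotatable-dihedral scan
#' energies) the weight is constant and inversely proportional to that
#' part's total sum of squares, then globally rescaled so the weights sum to
#' the number of observations. With these weights the weighted residual sum
#' of squares equals `N_parts - sum(R^2_part)` up to the penalty, so the fit
#' maximizes the sum of the per-part R-squared values. Rescaling all weights
#' by a constant changes nothing reported.
#' @param Y observation vector
#' @param part factor of part labels per observation
#' @return numeric weight vector summing to `length(Y)`
#' @export
observation_weights <- function(Y, part) {
  w <- numeric(length(Y))
  for (pp in levels(droplevels(part))) {
    i <- which(part == pp)
    sst <- sum(Y[i]^2)
    if (sst <= 0) stop("training part '", pp, "' has zero total sum of squares")
    w[i] <- 1 / sst
  }
  w * length(Y) / sum(w)
}

#' Penalty factors per predictor
#'
#' `nu_j` proportional to the weighted root sum of squares of column `j`, so
#' that `nu_j * |beta_j|` is independent of measurement units; rescaled to
#' sum to the number of predictors. All-zero columns get `nu = 0` with a
#' warning (they can never activate anyway).
#' @param M design matrix
#' @param w observation weights
#' @return numeric vector of penalty factors
#' @export
penalty_factors <- function(M, w) {
  nu <- sqrt(as.numeric(crossprod(M^2, w)) / length(w))
  if (any(nu == 0)) {
    warning(sum(nu == 0), " all-zero design column(s); penalty factor 0")
  }
  pos <- nu > 0
  if (any(pos)) nu <- nu * sum(pos) / sum(nu)
  nu
}

#' Bounded weighted LASSO along a geometric lambda path
#'
#' Minimizes `(1/(2N)) sum_i w_i (Y_i - M_i beta)^2 +
#' lambda sum_j nu_j |beta_j|` subject to `lb_j <= beta_j <= ub_j`, by cyclic
#' coordinate descent with soft-thresholding, box clipping and warm starts.
#' `lambda_max` is computed as the smallest value zeroing every coefficient;
#' the path descends geometrically to `lambda_max * lambda_ratio`.
#'
#' @param M design matrix
#' @param Y observations
#' @param w observation weights
#' @param nu penalty factors
#' @param lb,ub box bounds
#' @param n_lambda path length (default 100)
#' @param lambda_ratio `lambda_min/lambda_max` (default 1e-5)
#' @param thresh convergence threshold on the scaled coefficient updates
#' @param max_iter sweep cap per lambda
#' @return object of class `lasso_path`: list with `lambda` (descending),
#'   `beta` (p x n_lambda), `n_nonzero`
#' @export
lasso_path <- function(M, Y, w, nu, lb, ub, n_lambda = 100L,
                       lambda_ratio = 1e-5, thresh = 1e-10,
                       max_iter = 100000L) {
  n <- length(Y)
  p <- ncol(M)
  wM <- M * w
  z <- as.numeric(colSums(wM * M)) / n          # curvature per coordinate
  kappa <- as.numeric(crossprod(wM, Y)) / n     # gradient at beta = 0
  ## smallest lambda keeping beta = 0 optimal: only the feasible activation
  ## direction matters for bound-constrained coordinates
  up <- ifelse(ub > 0, pmax(kappa, 0), 0)
  dn <- ifelse(lb < 0, pmax(-kappa, 0), 0)
  cand <- ifelse(nu > 0, pmax(up, dn) / ifelse(nu > 0, nu, 1), 0)
  lambda_max <- max(cand, 0)
  if (lambda_max == 0) lambda_max <- 1
  lambda <- lambda_max * lambda_ratio^(seq(0, 1, length.out = n_lambda))
  beta <- matrix(0, p, n_lambda)
  b <- numeric(p)
  r <- Y                                        # residual at beta = 0
  y_ss <- sum(w * Y^2) / n
  active <- which(z > 0)
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    it <- 0L
    repeat {
      it <- it + 1L
      delta_max <- 0
      for (j in active) {
        bj <- b[j]
        rho <- sum(wM[, j] * r) / n + z[j] * bj
        ## soft-threshold, then clip to the box
        bnew <- if (rho > lam * nu[j]) (rho - lam * nu[j]) / z[j]
          else if (rho < -lam * nu[j]) (rho + lam * nu[j]) / z[j]
          else 0
        bnew <- min(max(bnew, lb[j]), ub[j])
        if (bnew != bj) {
          r <- r - M[, j] * (bnew - bj)
          b[j] <- bnew
          delta_max <- max(delta_max, z[j] * (bnew - bj)^2)
        }
      }
      if (delta_max < thresh * y_ss) break
      if (it >= max_iter) {
        stop("coordinate descent did not converge at lambda = ", lam)
      }
    }
    beta[, li] <- b
  }
  structure(list(lambda = lambda, beta = beta,
                 n_nonzero = colSums(beta != 0), lambda_max = lambda_max),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso_path: %d lambda values in [%.3g, %.3g], %d..%d nonzero\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$n_nonzero), max(x$n_nonzero)))
  invisible(x)
}

#' Select the best regularization strength on the path
#'
#' Walks the path from the least-regularized end. Among path points sharing a
#' count of surviving force constants, the one with the highest combined
#' training R-squared represents that count. A force constant is kept iff
#' excluding it would increase the SSE by more than half the formal amount
#' per degree of freedom (the residual SSE divided by `dof = 3 * N_atoms`),
#' so moving to the next sparser model is accepted while the finite
#' difference
#' `dof * (R2_a - R2_b) / ((N_parts - R2_a) * (Nk_a - Nk_b)) <= 1/2`
#' holds, with `R2` the sum of per-part training R-squared values (the
#' total sum of squares cancels out of the test). `lambda_best` is the last
#' accepted point.
#'
#' @param path a `lasso_path`
#' @param M,Y,part design, observations and part labels used for the fit
#' @param n_atoms_ atom count defining the degrees of freedom
#' @return list with `lambda_best`, `index`, `beta` (coefficients at the
#'   selection), `n_k_remaining`, and the walk table `steps`
#' @export
select_lambda_best <- function(path, M, Y, part, n_atoms_) {
  if (length(path$lambda) < 2L) stop("lambda path too short")
  r2_sum <- vapply(seq_along(path$lambda), function(li) {
    pred <- as.numeric(M %*% path$beta[, li])
    sum(vapply(levels(part), function(pp) {
      i <- which(part == pp)
      1 - sum((Y[i] - pred[i])^2) / sum(Y[i]^2)
    }, numeric(1L)))
  }, numeric(1L))
  ord <- order(path$lambda)                 # ascending lambda
  nk <- path$n_nonzero[ord]
  r2 <- r2_sum[ord]
  ## best representative per distinct surviving-k count, walking upward
  counts <- unique(nk)
  reps <- vapply(counts, function(ck) {
    cand <- which(nk == ck)
    cand[which.max(r2[cand])]
  }, integer(1L))
  dof <- 3 * n_atoms_
  n_parts <- nlevels(droplevels(part))
  acc <- reps[1L]
  steps <- list()
  if (length(reps) > 1L) {
    for (s in 2:length(reps)) {
      a <- acc; bidx <- reps[s]
      dnk <- nk[a] - nk[bidx]
      sse_a <- n_parts - r2[a]           # weighted SSE in SST units
      stat <- if (dnk > 0) {
        dof * (r2[a] - r2[bidx]) / (max(sse_a, .Machine$double.eps) * dnk)
      } else Inf
      steps[[length(steps) + 1L]] <- data.frame(
        lambda_a = path$lambda[ord][a], lambda_b = path$lambda[ord][bidx],
        nk_a = nk[a], nk_b = nk[bidx], stat = stat,
        accepted = stat <= 0.5)
      if (stat > 0.5) break
      acc <- bidx
    }
  }
  li <- ord[acc]
  list(lambda_best = path$lambda[li], index = li, beta = path$beta[, li],
       n_k_remaining = path$n_nonzero[li],
       steps = if (length(steps)) do.call(rbind, steps) else data.frame())
}

#' Training/validation statistics of a fitted model
#'
#' No-intercept conventions: `SST = sum(Y^2)` per part (scan energies are
#' already centered), `R^2 = 1 - SSE/SST`, `RMSE = sqrt(SSE / n_rows)`.
#' Per-atom statistics pool each atom's three force components across all
#' geometries of the part.
#' @param beta fitted force constants
#' @param design a design list from [build_design()]
#' @param per_atom also compute per-atom statistics on the force rows
#' @return data frame of parts plus (optionally) attribute `per_atom`
#' @export
compute_statistics <- function(beta, design, per_atom = FALSE) {
  pred <- as.numeric(design$M %*% beta)
  res <- design$Y - pred
  out <- do.call(rbind, lapply(levels(droplevels(design$part)), function(pp) {
    i <- which(design$part == pp)
    sse <- sum(res[i]^2); sst <- sum(design$Y[i]^2)
    data.frame(part = pp, n = length(i), SSE = sse, SST = sst,
               R2 = 1 - sse / sst, RMSE = sqrt(sse / length(i)))
  }))
  if (per_atom) {
    fi <- which(design$part == "forces")
    atoms <- design$atom[fi]
    pa <- do.call(rbind, lapply(sort(unique(atoms)), function(a) {
      i <- fi[atoms == a]
      sse <- sum(res[i]^2); sst <- sum(design$Y[i]^2)
      data.frame(atom = a, n = length(i), SSE = sse, SST = sst,
                 R2 = 1 - sse / sst, RMSE = sqrt(sse / length(i)))
    }))
    attr(out, "per_atom") <- pa
  }
  out
}
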
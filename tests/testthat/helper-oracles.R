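# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain normal equations, explicit double loops,
# and quadrature.

# closed-form least squares via normal equations (no lm)
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# explicit per-fold refit PRESS using normal equations only
press_oracle <- function(data, response, descriptors, fold_id) {
  y <- data[[response]]
  X <- as.matrix(data[descriptors])
  press <- 0
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    beta <- ols_oracle(X[!hold, , drop = FALSE], y[!hold])
    pred <- drop(cbind(1, X[hold, , drop = FALSE]) %*% beta)
    press <- press + sum((y[hold] - pred)^2)
  }
  press
}

# brute-force O(N^2) contact-residue oracle: double loop over atom pairs
contacts_oracle <- function(structure, cutoff) {
  a <- structure$atoms
  sel <- a$residue_name %in% structure$ligand_resname
  lig <- a[sel & !a$is_hydrogen, ]
  prot <- a[!sel & !a$is_hydrogen, ]
  hits <- list()
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(prot))) {
      d <- sqrt((lig$x[i] - prot$x[j])^2 + (lig$y[i] - prot$y[j])^2 +
                  (lig$z[i] - prot$z[j])^2)
      if (d < cutoff) {
        key <- paste(prot$residue_name[j], prot$residue_number[j],
                     prot$chain[j])
        hits[[key]] <- min(hits[[key]] %||% Inf, d)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(key = character(), min_d = numeric()))
  }
  data.frame(key = names(hits), min_d = unlist(hits), row.names = NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# residue keys of a package contact report, for set comparison
report_keys <- function(report) {
  sort(paste(report$residue_name, report$residue_number, report$chain))
}

# apply a random rigid transform (rotation + translation) to a structure
rigid_transform <- function(structure, seed) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- rnorm(3, sd = 2)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new_xyz <- xyz %*% R + matrix(t_vec, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- new_xyz[, 1]
  structure$atoms$y <- new_xyz[, 2]
  structure$atoms$z <- new_xyz[, 3]
  structure
}

# Boltzmann-inversion reference profile for a potential, min-zero, at the
# same bin centres (normalisation by quadrature cancels in the shift)
boltzmann_reference <- function(U, xi) {
  g <- U(xi)
  g - min(g)
}
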
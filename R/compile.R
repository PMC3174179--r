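## Fast right-hand side used by the integrator. The readable, generic
## engine (evaluate_rates / evaluate_rhs) resolves parameters by name at
## every call; inside lsoda that cost dominates, so the model is "compiled"
## once into flat index vectors and the per-step work is a handful of
## vectorized operations. The two paths are required to agree exactly
## (see the test suite); the compiled path is an optimization, not a
## second model.

.compile_model <- function(model) {
  net <- model$network
  p <- model$params
  sp <- net$species
  nr <- length(net$reactions)
  keff <- numeric(nr)           # rate constant x constant factors
  iA <- integer(nr); iB <- integer(nr)  # reactant indices (0 = none)
  kind <- integer(nr)           # 1 mass action, 2 saturable
  km <- numeric(nr)
  iM <- integer(nr); kM <- numeric(nr)  # modulation species / half-sat
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    k <- p[[r$rate_constant]]
    for (f in r$factor) k <- k * p[[f]]
    keff[j] <- k
    if (r$kind == "saturable_supply") {
      kind[j] <- 2L
      iA[j] <- match(names(r$reactants)[1], sp)
      km[j] <- p[[r$km]]
    } else {
      kind[j] <- 1L
      ord <- r$reactants
      idx <- match(names(ord), sp)
      ## at most bimolecular (order 2 encoded as repeated index)
      stopifnot(sum(ord) <= 2)
      iA[j] <- idx[1]
      iB[j] <- if (ord[1] == 2) idx[1] else if (length(idx) > 1) idx[2] else 0L
    }
    if (!is.null(r$modulation)) {
      iM[j] <- match(r$modulation$species, sp)
      kM[j] <- p[[r$modulation$km]]
    }
  }
  S <- stoichiometry_matrix(net)
  clamp_idx <- if (length(model$clamp)) match(names(model$clamp), sp) else
    integer(0)
  clamp_val <- unname(model$clamp)
  sat <- which(kind == 2L)
  mod <- which(iM > 0L)
  hasB <- which(iB > 0L)
  function(t, y, parms) {
    y <- pmax(y, 0)
    if (length(clamp_idx)) y[clamp_idx] <- clamp_val
    rates <- keff * y[iA]
    if (length(hasB)) rates[hasB] <- rates[hasB] * y[iB[hasB]]
    if (length(sat))
      rates[sat] <- keff[sat] * y[iA[sat]] / (km[sat] + y[iA[sat]])
    if (length(mod))
      rates[mod] <- rates[mod] * y[iM[mod]] / (y[iM[mod]] + kM[mod])
    dy <- drop(S %*% rates)
    if (length(clamp_idx)) dy[clamp_idx] <- 0
    list(dy)
  }
}
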
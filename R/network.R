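## Concentrations below this magnitude are treated as zero when rate laws are
## evaluated; integrator overshoot can leave states a hair below zero and the
## rate laws must stay non-negative on the closed orthant.
.CONC_TOL <- 1e-12

#' Construct a reaction for a mass-action network
#'
#' A reaction couples a rate law to a stoichiometry. Three rate-law kinds are
#' supported: plain (bi)molecular mass action, a saturable (Michaelis-type)
#' supply term, and first-order membrane permeation scaled by an aggregate
#' surface factor. Rate constants are referenced by name and resolved against
#' the model's parameter vector, so interventions that rescale a constant
#' apply to every reaction using it.
#'
#' @param id reaction identifier, e.g. `"R1"`.
#' @param kind one of `"bimolecular_mass_action"`, `"saturable_supply"`,
#'   `"permeation"`.
#' @param rate_constant name of the rate-constant parameter (for
#'   `saturable_supply` this is the maximal-rate parameter, units M/s).
#' @param reactants named numeric vector of kinetic orders; for mass action
#'   the rate is `k * prod(conc^order)`. Entries are also consumed with
#'   stoichiometry equal to `abs(stoich)` given in `consumes`.
#' @param consumes,produces named numeric vectors of stoichiometric
#'   coefficients (positive numbers); defaults derive `consumes` from
#'   `reactants` at coefficient 1.
#' @param km name of the half-saturation parameter (`saturable_supply` only).
#' @param factor names of constant multiplier parameters (e.g. the aggregate
#'   surface factor of a permeation term, or an enzyme concentration); their
#'   product scales the rate.
#' @param modulation optional `list(species=, km=)` applying a dimensionless
#'   saturable factor `[S]/([S] + K)` to the rate (used for the
#'   drug-dependence of NADPH-oxidase activity).
#' @return an object of class `dox_reaction`.
#' @export
dox_reaction <- function(id, kind, rate_constant, reactants,
                         consumes = NULL, produces = character(),
                         km = NULL, factor = character(),
                         modulation = NULL) {
  kind <- match.arg(kind,
    c("bimolecular_mass_action", "saturable_supply", "permeation"))
  if (kind == "saturable_supply" && is.null(km))
    stop("saturable_supply reaction ", id, " needs a `km` parameter name")
  if (is.null(consumes)) {
    consumes <- rep(1, length(reactants))
    names(consumes) <- names(reactants)
  }
  structure(list(id = id, kind = kind, rate_constant = rate_constant,
                 reactants = reactants, consumes = consumes,
                 produces = produces, km = km, factor = factor,
                 modulation = modulation),
            class = "dox_reaction")
}

#' Assemble a reaction network
#'
#' @param species character vector of unique species identifiers, in state
#'   order.
#' @param reactions list of [dox_reaction()] objects.
#' @param units concentration units (all species are molar).
#' @return an object of class `dox_network`.
#' @export
dox_network <- function(species, reactions, units = "M") {
  if (anyDuplicated(species))
    stop("duplicate species identifier: ",
         species[duplicated(species)][1])
  for (r in reactions) {
    ref <- unique(c(names(r$reactants), names(r$consumes), names(r$produces),
                    if (!is.null(r$modulation)) r$modulation$species))
    bad <- setdiff(ref, species)
    if (length(bad))
      stop("reaction ", r$id, " references unknown species: ",
           paste(bad, collapse = ", "))
  }
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  names(reactions) <- ids
  structure(list(species = species, reactions = reactions, units = units),
            class = "dox_network")
}

## Resolve a parameter by name, failing loudly with the missing symbol.
.param <- function(params, name, id) {
  if (!name %in% names(params) || is.na(params[[name]]))
    stop("reaction ", id, ": parameter `", name, "` is not set", call. = FALSE)
  params[[name]]
}

.reaction_rate <- function(r, params, conc) {
  k <- .param(params, r$rate_constant, r$id)
  fac <- 1
  for (f in r$factor) fac <- fac * .param(params, f, r$id)
  rate <- switch(r$kind,
    bimolecular_mass_action = {
      k * fac * prod(conc[names(r$reactants)]^r$reactants)
    },
    permeation = {
      k * fac * conc[[names(r$reactants)[1]]]
    },
    saturable_supply = {
      s <- conc[[names(r$reactants)[1]]]
      km <- .param(params, r$km, r$id)
      k * fac * s / (km + s)
    })
  if (!is.null(r$modulation)) {
    s <- conc[[r$modulation$species]]
    rate <- rate * s / (s + .param(params, r$modulation$km, r$id))
  }
  unname(rate)
}

#' Evaluate all reaction rates at a state
#'
#' Concentrations a hair below zero (integrator overshoot) are clamped to
#' zero for rate evaluation only; the state itself is never modified. Species
#' listed in `model$clamp` are fixed at their clamp value.
#'
#' @param model a `dox_model`.
#' @param state named concentration vector (M); defaults to the model's
#'   initial state.
#' @return named numeric vector of reaction rates (M/s).
#' @export
evaluate_rates <- function(model, state = model$state0) {
  net <- model$network
  miss <- setdiff(net$species, names(state))
  if (length(miss))
    stop("state is missing species: ", paste(miss, collapse = ", "))
  conc <- pmax(state[net$species], 0)
  if (length(model$clamp))
    conc[names(model$clamp)] <- model$clamp
  vapply(net$reactions, .reaction_rate, numeric(1),
         params = model$params, conc = conc)
}

#' Stoichiometry matrix of a network
#'
#' Rows are species, columns reactions; `S %*% rates` equals the right-hand
#' side of the ODE system. Entries are signed stoichiometric coefficients and
#' may be non-integer where a reaction couples compartments of different
#' volume (membrane transport concentrates uptake into the much smaller
#' cytosolic volume).
#'
#' @param network a `dox_network` (a `dox_model` is also accepted).
#' @return numeric species-by-reaction matrix.
#' @export
stoichiometry_matrix <- function(network) {
  if (inherits(network, "dox_model")) network <- network$network
  S <- matrix(0, length(network$species), length(network$reactions),
              dimnames = list(network$species, names(network$reactions)))
  for (r in network$reactions) {
    S[names(r$consumes), r$id] <- S[names(r$consumes), r$id] - r$consumes
    if (length(r$produces))
      S[names(r$produces), r$id] <- S[names(r$produces), r$id] + r$produces
  }
  S
}

#' Time derivatives of all species at a state
#'
#' Stoichiometry-weighted sum of the mass-action reaction rates. Clamped
#' species have derivative zero.
#'
#' @inheritParams evaluate_rates
#' @return named numeric vector of d(concentration)/dt (M/s).
#' @export
evaluate_rhs <- function(model, state = model$state0) {
  rates <- evaluate_rates(model, state)
  dy <- drop(stoichiometry_matrix(model$network) %*% rates)
  if (length(model$clamp)) dy[names(model$clamp)] <- 0
  dy
}

#' @export
print.dox_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) {
    lhs <- paste(names(r$consumes), collapse = " + ")
    rhs <- paste(names(r$produces), collapse = " + ")
    cat(sprintf("  %-4s %-24s [%s, %s]\n", r$id,
                paste(lhs, "->", rhs), r$kind, r$rate_constant))
  }
  invisible(x)
}
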
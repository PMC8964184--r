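# Candidate island-model set and its backward-time rendering.
#
# Forward semantics shared by all models: a single ancestral population of
# size nuA (Nref units) splits at backward time T (or T1 + T2); immediately
# after the split population 1 has size nuA*(1 - s) and population 2 (the
# derived "island") nuA*s. The size trajectory then follows the model's
# growth mode and migration is switched on per epoch by its migration mode.
# Sizes are ratios to Nref, durations are in 2*Nref generations, and
# migration rates are 2*Nref*m with m the per-generation migrant fraction;
# m12 is the rate INTO population 1 FROM population 2.

default_bounds <- function() list(
  size = c(1e-3, 100),       # nuA, nu1, nu2
  time = c(1e-3, 15),        # T, T1, T2
  time_recent = c(1e-3, 0.05),  # split-time bound of recent-founder models
  s = c(1e-3, 0.5),
  migration = c(0, 20)
)

param_kind <- function(name) {
  switch(name,
    nuA = , nu1 = , nu2 = "size",
    T = , T1 = , T2 = "time",
    s = "s",
    m12 = , m21 = "migration",
    stop("unknown parameter: ", name)
  )
}

new_model <- function(name, scenario, growth, migration, params, bounds = NULL) {
  b <- default_bounds()
  free <- lapply(params, function(p) {
    k <- param_kind(p)
    if (k == "time" && scenario == "founder_recent") b$time_recent else b[[k]]
  })
  names(free) <- params
  if (!is.null(bounds)) free[names(bounds)] <- bounds
  structure(
    list(name = name, scenario = scenario, growth = growth,
         migration = migration, free_params = free, k = length(free)),
    class = "demographic_model"
  )
}

#' @export
#' @method print demographic_model
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s [%s / %s / %s], k = %d\n  free: %s\n",
              x$name, x$scenario, x$growth, x$migration, x$k,
              paste(names(x$free_params), collapse = ", ")))
  invisible(x)
}

#' Registry of candidate two-population island models
#'
#' "Island" refers to the derived, recently founded population; the three
#' scenarios are old vicariance, old founder event, and recent founder event
#' (the last encoded as the founder topology with a split-time upper bound
#' an order of magnitude smaller). Size trajectories are constant since the
#' split, two-epoch (founding sizes then present sizes), or continuous
#' exponential growth; migration is absent, continuous, ancestral-then-
#' isolation, or secondary contact.
#'
#' @param comparison `"full"` (all eight models), `"vicariance_family"`, or
#'   `"founder_family"`.
#' @return list of `demographic_model` objects.
#' @export
model_registry <- function(comparison = "full") {
  p_const_T <- c("nuA", "nu1", "nu2", "T", "s")
  p_two_T12 <- c("nuA", "nu1", "nu2", "T1", "T2", "s")
  mig <- c("m12", "m21")
  models <- list(
    new_model("vic_no_mig", "vicariance", "constant", "none", p_const_T),
    new_model("vic_sec_contact_asym_mig", "vicariance", "constant",
              "secondary_contact", c(p_two_T12, mig)),
    new_model("founder_sec_contact_asym_two_epoch", "founder_old", "two_epoch",
              "secondary_contact", c(p_two_T12, mig)),
    new_model("founder_anc_asym_two_epoch", "founder_old", "two_epoch",
              "ancestral_then_isolation", c(p_two_T12, mig)),
    new_model("founder_no_mig_exp", "founder_old", "exp_growth", "none",
              p_const_T),
    new_model("founder_continuous_asym_mig_exp", "founder_old", "exp_growth",
              "continuous", c(p_const_T, mig)),
    new_model("founder_recent_no_mig", "founder_recent", "exp_growth", "none",
              p_const_T),
    new_model("founder_recent_asym_mig", "founder_recent", "exp_growth",
              "continuous", c(p_const_T, mig))
  )
  names(models) <- vapply(models, `[[`, character(1), "name")
  switch(comparison,
    full = models,
    vicariance_family = models[vapply(models, function(m)
      m$scenario == "vicariance", logical(1))],
    founder_family = models[vapply(models, function(m)
      m$scenario != "vicariance", logical(1))],
    stop("unknown comparison tag: ", comparison)
  )
}

#' Validate a parameter set against a model's bounds
#'
#' @param model a `demographic_model`
#' @param p named numeric vector / list of parameter values
#' @return character vector of violations; length 0 when valid.
#' @export
validate_params <- function(model, p) {
  p <- unlist(p)
  viol <- character(0)
  miss <- setdiff(names(model$free_params), names(p))
  if (length(miss))
    viol <- c(viol, paste("missing parameter:", miss))
  for (nm in intersect(names(model$free_params), names(p))) {
    b <- model$free_params[[nm]]
    v <- p[[nm]]
    if (!is.finite(v) || v < b[1] || v > b[2])
      viol <- c(viol, sprintf("%s = %g outside [%g, %g]", nm, v, b[1], b[2]))
  }
  viol
}

#' Render a model and parameter set as a backward-time epoch schedule
#'
#' Epochs are ordered most recent first; at the split all population-2
#' lineages join the ancestral deme of size `nuA`. Deme sizes within an
#' epoch are constant or exponential between endpoint sizes.
#'
#' @inheritParams validate_params
#' @return An object of class `epoch_schedule`: list of epochs
#'   (`duration`, `size1`, `size2`, `growth1`, `growth2` backward rates,
#'   `m12`, `m21`, `ndemes`), ending in the unbounded single-deme epoch.
#' @export
to_epochs <- function(model, p) {
  p <- as.list(unlist(p))
  viol <- validate_params(model, p)
  if (length(viol))
    stop("invalid parameters for ", model$name, ": ",
         paste(viol, collapse = "; "))
  found1 <- p$nuA * (1 - p$s)   # population 1 just after the split (forward)
  found2 <- p$nuA * p$s         # derived population just after the split
  two_ep <- model$growth == "two_epoch" ||
    model$migration %in% c("secondary_contact", "ancestral_then_isolation")

  mig_in <- function(which_epoch) {  # which_epoch: "recent" or "old"
    on <- switch(model$migration,
      none = FALSE,
      continuous = TRUE,
      secondary_contact = which_epoch == "recent",
      ancestral_then_isolation = which_epoch == "old"
    )
    if (on) c(p$m12, p$m21) else c(0, 0)
  }

  epochs <- list()
  if (two_ep) {
    sz_old <- if (model$growth == "two_epoch") c(found1, found2)
              else c(p$nu1, p$nu2)  # constant-size models keep nu1/nu2 throughout
    epochs[[1]] <- epoch(p$T2, p$nu1, p$nu2, mig = mig_in("recent"))
    epochs[[2]] <- epoch(p$T1, sz_old[1], sz_old[2], mig = mig_in("old"))
  } else if (model$growth == "exp_growth") {
    # backward: nu_i at time 0 shrinking to the founding size at the split
    epochs[[1]] <- epoch(p$T, p$nu1, p$nu2,
                         growth = c(log(found1 / p$nu1) / p$T,
                                    log(found2 / p$nu2) / p$T),
                         mig = mig_in("recent"))
  } else {  # constant
    epochs[[1]] <- epoch(p$T, p$nu1, p$nu2, mig = mig_in("recent"))
  }
  epochs[[length(epochs) + 1]] <- epoch(Inf, p$nuA, NA, ndemes = 1L)
  structure(list(epochs = epochs, model = model$name, params = p),
            class = "epoch_schedule")
}

#' Construct a single epoch (building block for custom schedules)
#'
#' @param duration epoch length in `2 Nref` generations (`Inf` for the last)
#' @param size1,size2 deme sizes at the epoch's recent end (Nref units)
#' @param growth backward exponential rates per deme (size grows as
#'   `size * exp(growth * tau)` with `tau` the time into the epoch)
#' @param mig scaled migration rates `c(m12, m21)` (Table-2 convention)
#' @param ndemes 2 before the merge, 1 after
#' @return list describing one epoch
#' @export
epoch <- function(duration, size1, size2 = NA, growth = c(0, 0),
                  mig = c(0, 0), ndemes = 2L) {
  if (ndemes == 2L && (!is.finite(size2) || size2 <= 0))
    stop("two-deme epoch needs a positive size2")
  if (!is.finite(size1) || size1 <= 0) stop("deme sizes must be positive")
  list(duration = duration, size1 = size1, size2 = size2,
       growth1 = growth[1], growth2 = growth[2],
       m12 = mig[1], m21 = mig[2], ndemes = as.integer(ndemes))
}

#' Assemble an epoch schedule from epochs
#'
#' @param ... epochs from [epoch()], most recent first; the last must be the
#'   unbounded single-deme epoch.
#' @return An `epoch_schedule`.
#' @export
epoch_schedule <- function(...) {
  eps <- list(...)
  last <- eps[[length(eps)]]
  if (is.finite(last$duration) || last$ndemes != 1L)
    stop("the final epoch must be single-deme with infinite duration")
  structure(list(epochs = eps, model = "custom", params = list()),
            class = "epoch_schedule")
}

# Flatten an epoch_schedule into the numeric matrix the C++ engine consumes.
# Backward per-lineage migration rates are m/2 under the 2*Nref*m scaling.
schedule_matrix <- function(schedule) {
  eps <- schedule$epochs
  m <- matrix(0, nrow = length(eps), ncol = 8)
  for (k in seq_along(eps)) {
    e <- eps[[k]]
    m[k, ] <- c(e$duration, e$size1, e$growth1,
                ifelse(is.na(e$size2), 1, e$size2), e$growth2,
                e$m12 / 2, e$m21 / 2, e$ndemes)
  }
  m
}
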
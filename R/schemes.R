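SCHEME_IDS <- c("S1", "S2", "S3", "S4")

#' Construct a kinetic scheme for RNA polymerase multi-nucleotide addition
#'
#' Builds one of the four first-order kinetic schemes used to describe
#' quench-flow multi-nucleotide addition time courses:
#'
#' * `S1` — irreversible elongation chain for Pol I under vehicle:
#'   `EC10 -> EC11 -> ... -> EC19` with per-step observed rate constants
#'   `k1..k9`, plus an intrinsic-nuclease loss path `EC10 -> sink` (`k10`).
#' * `S2` — `S1` extended with two off-pathway paused states at the 11-mer
#'   and 12-mer (`EC11 <-> EC11p`, `EC12 <-> EC12p`; rates
#'   `kon1/koff1`, `kon2/koff2`). Paused complexes cannot elongate; they
#'   must revert to the active state before the next nucleotide is added.
#'   Describes Pol I in the presence of the inhibitor BMH-21.
#' * `S3` — fully reversible chain `EC10 <-> ... <-> EC19`
#'   (`kF1..kF9`, `kR1..kR9`) for Pol II, whose slow pyrophosphate release
#'   permits the reverse reaction (pyrophosphorolysis). No nuclease path.
#' * `S4` — `S1` plus activation of an initially inactive subpopulation,
#'   `EC10i -> EC10` (`kact`), for Pol III. The initial mass is split
#'   `(1 - f_inactive, f_inactive)` between `EC10` and `EC10i`;
#'   `f_inactive` is supplied with the rate parameters.
#'
#' Species are ordered `EC10..EC19`, then paused species by length, then
#' `EC10i`, then the cleaved sink, so repeated calls are byte-identical.
#'
#' @param scheme_id one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param cleaved_band optional integer RNA length (7–19) at which the
#'   nuclease cleavage product appears as a detectable gel band. The default
#'   `NA` treats the cleaved RNA as invisible (it leaves the quantified
#'   lane signal).
#' @return an object of class `kinetic_scheme`: a list with elements
#'   `scheme_id`, `species` (data frame: `name`, `rna_length`, `state_tag`),
#'   `transitions` (data frame: `from`, `to`, `rate_name`) and `initial`
#'   (named fractions; for `S4` the split is resolved against
#'   `f_inactive` at solve time).
#' @seealso [rate_matrix()], [solve_timecourse()], [scheme_to_json()]
#' @export
#' @examples
#' s1 <- build_scheme("S1")
#' nrow(s1$species)      # 11: EC10..EC19 + cleaved sink
#' nrow(s1$transitions)  # 10: nine addition steps + nuclease
build_scheme <- function(scheme_id, cleaved_band = NA) {
  if (!is.character(scheme_id) || length(scheme_id) != 1L ||
      !scheme_id %in% SCHEME_IDS) {
    stop("unknown scheme_id: must be one of ", paste(SCHEME_IDS, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(cleaved_band)) {
    cleaved_band <- as.integer(cleaved_band)
    stopifnot(cleaved_band >= 7L, cleaved_band <= 19L)
  }

  ec <- function(len) sprintf("EC%d", len)
  active <- data.frame(name = ec(10:19), rna_length = 10:19,
                       state_tag = "active", stringsAsFactors = FALSE)
  sink <- data.frame(name = "sink",
                     rna_length = if (is.na(cleaved_band)) NA_integer_ else cleaved_band,
                     state_tag = "cleaved_sink", stringsAsFactors = FALSE)

  chain_fwd <- data.frame(from = ec(10:18), to = ec(11:19),
                          rate_name = sprintf("k%d", 1:9),
                          stringsAsFactors = FALSE)
  nuclease <- data.frame(from = "EC10", to = "sink", rate_name = "k10",
                         stringsAsFactors = FALSE)

  if (scheme_id == "S1") {
    species <- rbind(active, sink)
    transitions <- rbind(chain_fwd, nuclease)
    initial <- c(EC10 = 1)
  } else if (scheme_id == "S2") {
    paused <- data.frame(name = c("EC11p", "EC12p"), rna_length = c(11L, 12L),
                         state_tag = "paused", stringsAsFactors = FALSE)
    species <- rbind(active, paused, sink)
    pause_tr <- data.frame(
      from = c("EC11", "EC11p", "EC12", "EC12p"),
      to   = c("EC11p", "EC11", "EC12p", "EC12"),
      rate_name = c("kon1", "koff1", "kon2", "koff2"),
      stringsAsFactors = FALSE)
    transitions <- rbind(chain_fwd, pause_tr, nuclease)
    initial <- c(EC10 = 1)
  } else if (scheme_id == "S3") {
    species <- active
    chain_rev <- data.frame(from = ec(11:19), to = ec(10:18),
                            rate_name = sprintf("kR%d", 1:9),
                            stringsAsFactors = FALSE)
    chain_fwd$rate_name <- sprintf("kF%d", 1:9)
    transitions <- rbind(chain_fwd, chain_rev)
    initial <- c(EC10 = 1)
  } else { # S4
    inactive <- data.frame(name = "EC10i", rna_length = 10L,
                           state_tag = "inactive", stringsAsFactors = FALSE)
    species <- rbind(active, inactive, sink)
    activation <- data.frame(from = "EC10i", to = "EC10", rate_name = "kact",
                             stringsAsFactors = FALSE)
    transitions <- rbind(chain_fwd, activation, nuclease)
    # placeholder split; resolved against f_inactive in initial_state()
    initial <- c(EC10 = 1)
  }

  rownames(species) <- rownames(transitions) <- NULL
  scheme <- structure(
    list(scheme_id = scheme_id, species = species,
         transitions = transitions, initial = initial),
    class = "kinetic_scheme")
  validate_scheme(scheme)
  scheme
}

#' Validate a kinetic scheme
#'
#' Checks structural invariants: species/state-tag compatibility (paused only
#' at lengths 11 and 12, inactive only at length 10), no self-transitions,
#' unique rate names per edge, initial fractions summing to 1, reachability of
#' every species from the initially populated ones, and absence of
#' length-decreasing transitions outside `S3` except the nuclease sink path.
#'
#' @param scheme a `kinetic_scheme`.
#' @return the scheme, invisibly; errors describe the violated invariant.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sp <- scheme$species
  tr <- scheme$transitions
  if (anyDuplicated(sp$name)) stop("duplicate species names", call. = FALSE)
  bad_pause <- sp$state_tag == "paused" & !sp$rna_length %in% c(11L, 12L)
  if (any(bad_pause)) stop("paused species only permitted at lengths 11 and 12",
                           call. = FALSE)
  bad_inact <- sp$state_tag == "inactive" & sp$rna_length != 10L
  if (any(bad_inact)) stop("inactive species only permitted at length 10",
                           call. = FALSE)
  if (any(tr$from == tr$to)) stop("self-transition not allowed", call. = FALSE)
  if (anyDuplicated(tr[, c("from", "to")])) {
    stop("duplicate transition between the same species pair", call. = FALSE)
  }
  if (!all(c(tr$from, tr$to) %in% sp$name)) {
    stop("transition references unknown species", call. = FALSE)
  }
  sink_names <- sp$name[sp$state_tag == "cleaved_sink"]
  if (any(tr$from %in% sink_names)) {
    stop("cleaved sink carries no outgoing transitions", call. = FALSE)
  }
  if (abs(sum(scheme$initial) - 1) > 1e-12) {
    stop("initial fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(scheme$initial) %in% sp$name)) {
    stop("initial state references unknown species", call. = FALSE)
  }
  # reachability from initially populated species (S4's EC10i is seeded
  # implicitly whenever f_inactive > 0, so count it as initial if present)
  seeds <- union(names(scheme$initial),
                 sp$name[sp$state_tag == "inactive"])
  reached <- seeds
  repeat {
    nxt <- unique(tr$to[tr$from %in% reached])
    grown <- union(reached, nxt)
    if (length(grown) == length(reached)) break
    reached <- grown
  }
  if (!all(sp$name %in% reached)) {
    stop("unreachable species: ",
         paste(setdiff(sp$name, reached), collapse = ", "), call. = FALSE)
  }
  if (scheme$scheme_id %in% c("S1", "S2", "S4")) {
    len <- stats::setNames(sp$rna_length, sp$name)
    to_sink <- tr$to %in% sink_names
    decreasing <- !to_sink & !is.na(len[tr$from]) & !is.na(len[tr$to]) &
      len[tr$to] < len[tr$from]
    if (any(decreasing)) {
      stop("length-decreasing transition outside the nuclease path",
           call. = FALSE)
    }
  }
  invisible(scheme)
}

#' Named rate-constant parameter sets
#'
#' Convenience constructor for the named nonnegative rate constants (units
#' s^-1) parameterizing a scheme: `k1..k9` (per-step RNA appearance), `k10`
#' (intrinsic nuclease), `kon1/koff1`, `kon2/koff2` (pause entry/exit),
#' `kF1..kF9`/`kR1..kR9` (Pol II forward/reverse), `kact` (Pol III
#' activation) and, for `S4`, the dimensionless initial inactive fraction
#' `f_inactive` in \[0, 1\].
#'
#' @param ... named scalar values, or a single named numeric vector.
#' @return a validated named numeric vector of class `rate_params`.
#' @export
#' @examples
#' rate_params(k1 = 40, k2 = 35, k10 = 0.2)
rate_params <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.numeric(args[[1]])) {
    values <- args[[1]]
  } else {
    values <- unlist(args)
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("all rate parameters must be named", call. = FALSE)
  }
  if (anyDuplicated(names(values))) stop("duplicate parameter names", call. = FALSE)
  if (any(!is.finite(values))) stop("rates must be finite", call. = FALSE)
  if (any(values < 0)) stop("rates must be nonnegative", call. = FALSE)
  if ("f_inactive" %in% names(values)) {
    f <- values[["f_inactive"]]
    if (f < 0 || f > 1) stop("f_inactive must lie in [0, 1]", call. = FALSE)
  }
  structure(values, class = "rate_params")
}

#' Names of the free parameters of a scheme
#'
#' The rate names appearing in the scheme's transitions, in transition order,
#' plus `f_inactive` for `S4`.
#'
#' @param scheme a `kinetic_scheme`.
#' @return character vector of parameter names.
#' @export
free_params <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  nm <- scheme$transitions$rate_name
  if (scheme$scheme_id == "S4") nm <- c(nm, "f_inactive")
  nm
}

#' Initial state vector of a scheme
#'
#' Resolves the scheme's initial mass distribution over its species. For `S4`
#' the split between active `EC10` and inactive `EC10i` is taken from
#' `params[["f_inactive"]]`.
#'
#' @param scheme a `kinetic_scheme`.
#' @param params a named parameter vector (needed only for `S4`).
#' @return numeric vector over `scheme$species$name`, summing to 1.
#' @export
initial_state <- function(scheme, params = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  x0 <- stats::setNames(numeric(nrow(scheme$species)), scheme$species$name)
  if (scheme$scheme_id == "S4") {
    if (is.null(params) || !"f_inactive" %in% names(params)) {
      stop("S4 requires f_inactive in params", call. = FALSE)
    }
    f <- unname(params[["f_inactive"]])
    if (f < 0 || f > 1) stop("f_inactive must lie in [0, 1]", call. = FALSE)
    x0["EC10"] <- 1 - f
    x0["EC10i"] <- f
  } else {
    x0[names(scheme$initial)] <- scheme$initial
  }
  x0
}

#' First-order rate-generator matrix of a scheme
#'
#' Assembles the mass-action generator `K` of the linear system
#' `dx/dt = K x`: for each transition the off-diagonal entry
#' `K[target, source]` is its rate constant, and each diagonal entry is minus
#' the total outgoing rate of that species. Columns therefore sum to zero,
#' which expresses conservation of total complex mass (the nuclease product
#' is an explicit sink species, not a leak).
#'
#' @param scheme a `kinetic_scheme`.
#' @param params named numeric vector supplying every `rate_name` used by the
#'   scheme's transitions; all rates must be nonnegative and finite.
#' @return square numeric matrix with species names on both dimensions.
#' @export
#' @examples
#' s1 <- build_scheme("S1")
#' p <- rate_params(setNames(c(rep(1, 9), 0.1), free_params(s1)))
#' colSums(rate_matrix(s1, p))  # all zero
rate_matrix <- function(scheme, params) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  needed <- scheme$transitions$rate_name
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rates <- unname(unlist(params)[needed])
  if (any(!is.finite(rates))) stop("rates must be finite", call. = FALSE)
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  nm <- scheme$species$name
  n <- length(nm)
  K <- matrix(0, n, n, dimnames = list(nm, nm))
  i_to <- match(scheme$transitions$to, nm)
  i_from <- match(scheme$transitions$from, nm)
  for (j in seq_along(rates)) {
    K[i_to[j], i_from[j]] <- K[i_to[j], i_from[j]] + rates[j]
    K[i_from[j], i_from[j]] <- K[i_from[j], i_from[j]] - rates[j]
  }
  K
}

#' Serialize a kinetic scheme to JSON
#'
#' Writes the species list, transitions and initial state so custom schemes
#' can be supplied without code changes.
#'
#' @param scheme a `kinetic_scheme`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  obj <- list(scheme_id = scheme$scheme_id,
              species = scheme$species,
              transitions = scheme$transitions,
              initial = as.list(scheme$initial))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a kinetic scheme from JSON
#'
#' @param input a file path or a JSON string produced by [scheme_to_json()].
#' @return a validated `kinetic_scheme`.
#' @export
scheme_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input)
  sp <- as.data.frame(obj$species, stringsAsFactors = FALSE)
  sp$rna_length <- as.integer(sp$rna_length)
  scheme <- structure(
    list(scheme_id = obj$scheme_id,
         species = sp,
         transitions = as.data.frame(obj$transitions, stringsAsFactors = FALSE),
         initial = unlist(obj$initial)),
    class = "kinetic_scheme")
  validate_scheme(scheme)
  scheme
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme %s: %d species, %d transitions>\n",
              x$scheme_id, nrow(x$species), nrow(x$transitions)))
  cat("parameters:", paste(free_params(x), collapse = ", "), "\n")
  invisible(x)
}
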
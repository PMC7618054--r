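# Species order. Positional: the stoichiometry matrix, the R and C derivative
# routines, and the state constructors all share it.
.tcs_species <- c("S", "Sp", "C", "Cp", "SpC", "SCp", "SC",
                  "P", "PCp", "M", "Gi", "Gm")

#' Molecular state of the AtoSC model
#'
#' The twelve species the reactions connect: free HK (`S`), phospho-HK (`Sp`),
#' free RR (`C`), phospho-RR (`Cp`), the three HK:RR complexes (`SpC`, `SCp`,
#' `SC`), free and occupied promoter (`P`, `PCp`), and the reporter cascade
#' (`M` mRNA, `Gi` immature GFP, `Gm` mature fluorescent GFP).
#'
#' @param ... named concentrations; unnamed species default to 0.
#' @return named numeric vector of class `tcs_state`.
#' @seealso [tcs_initial_state()] for the conventional starting point.
#' @export
tcs_state <- function(...) {
  y <- stats::setNames(numeric(length(.tcs_species)), .tcs_species)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments to tcs_state() must be named")
    unknown <- setdiff(names(dots), .tcs_species)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    y[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  if (any(!is.finite(y)) || any(y < 0))
    stop("species concentrations must be finite and >= 0")
  class(y) <- "tcs_state"
  y
}

#' Default initial condition: all protein free and unphosphorylated
#'
#' `S = S_tot`, `C = C_tot`, `P = P_tot`, everything else 0.
#'
#' @param params a [tcs_parameters()] object.
#' @return a [tcs_state()].
#' @export
tcs_initial_state <- function(params) {
  validate_tcs_parameters(params)
  tcs_state(S = params[["S_tot"]], C = params[["C_tot"]], P = params[["P_tot"]])
}

#' Explicit mass-action reaction network of the AtoSC model
#'
#' Returns the reaction set as a stoichiometry matrix (species x reactions)
#' plus one mass-action rate law per reaction.  Reversible bindings contribute
#' two rate laws (forward and reverse), giving 19 in total:
#' HK autophosphorylation/autodephosphorylation, the three HK:RR binding
#' equilibria, phosphotransfer, phosphatase action, promoter
#' binding/unbinding, leaky and induced transcription, translation, GFP
#' maturation, and first-order degradation of mRNA and of both GFP forms.
#'
#' HK, RR and promoter moieties are conserved by construction: every reaction
#' column sums to zero over each conservation group.
#'
#' @param params a [tcs_parameters()] object.
#' @return a list of class `tcs_reaction_network` with elements
#'   `stoichiometry` (12 x 19 integer matrix), `reactions` (data.frame with
#'   columns `name`, `rate_constant`, `description`), and `rates(state)`, a
#'   function returning the 19 mass-action fluxes at a state.
#' @examples
#' net <- build_reaction_network(tcs_parameters())
#' dim(net$stoichiometry)
#' net$rates(tcs_initial_state(tcs_parameters()))
#' @export
build_reaction_network <- function(params) {
  validate_tcs_parameters(params)
  p <- as.numeric(params)
  names(p) <- .tcs_param_names

  rxn <- list(
    # name            rate constant  reactants (consumed)   products
    list("autophosphorylation",  "k_ap",    c(S = 1),            c(Sp = 1)),
    list("autodephosphorylation","k_ad",    c(Sp = 1),           c(S = 1)),
    list("bind_SpC",             "k_b1",    c(Sp = 1, C = 1),    c(SpC = 1)),
    list("unbind_SpC",           "k_d1",    c(SpC = 1),          c(Sp = 1, C = 1)),
    list("phosphotransfer",      "k_pt",    c(SpC = 1),          c(S = 1, Cp = 1)),
    list("bind_SCp",             "k_b2",    c(S = 1, Cp = 1),    c(SCp = 1)),
    list("unbind_SCp",           "k_d2",    c(SCp = 1),          c(S = 1, Cp = 1)),
    list("phosphatase",          "k_ph",    c(SCp = 1),          c(S = 1, C = 1)),
    list("bind_SC",              "k_b3",    c(S = 1, C = 1),     c(SC = 1)),
    list("unbind_SC",            "k_d3",    c(SC = 1),           c(S = 1, C = 1)),
    list("promoter_bind",        "k_bnd",   c(Cp = 1, P = 1),    c(PCp = 1)),
    list("promoter_unbind",      "k_unbnd", c(PCp = 1),          c(Cp = 1, P = 1)),
    list("leaky_transcription",  "k_lgexp", c(P = 1),            c(P = 1, M = 1)),
    list("induced_transcription","k_pmgexp",c(PCp = 1),          c(PCp = 1, M = 1)),
    list("translation",          "k_trl",   c(M = 1),            c(M = 1, Gi = 1)),
    list("maturation",           "k_mat",   c(Gi = 1),           c(Gm = 1)),
    list("mrna_degradation",     "d_m",     c(M = 1),            character(0)),
    list("gfp_i_degradation",    "d_g",     c(Gi = 1),           character(0)),
    list("gfp_m_degradation",    "d_g",     c(Gm = 1),           character(0))
  )

  n_rxn <- length(rxn)
  S <- matrix(0L, nrow = length(.tcs_species), ncol = n_rxn,
              dimnames = list(.tcs_species, vapply(rxn, `[[`, "", 1L)))
  for (j in seq_len(n_rxn)) {
    re <- rxn[[j]][[3L]]
    pr <- rxn[[j]][[4L]]
    if (length(re)) S[names(re), j] <- S[names(re), j] - as.integer(re)
    if (length(pr)) S[names(pr), j] <- S[names(pr), j] + as.integer(pr)
  }

  reactants <- lapply(rxn, `[[`, 3L)
  constants <- vapply(rxn, `[[`, "", 2L)

  rates <- function(state) {
    y <- as.numeric(state)
    names(y) <- .tcs_species
    v <- numeric(n_rxn)
    for (j in seq_len(n_rxn)) {
      v[j] <- p[[constants[j]]] * prod(y[names(reactants[[j]])])
    }
    names(v) <- colnames(S)
    v
  }

  structure(
    list(
      stoichiometry = S,
      reactions = data.frame(
        name = colnames(S),
        rate_constant = constants,
        description = vapply(seq_len(n_rxn), function(j) {
          re <- reactants[[j]]
          pr <- rxn[[j]][[4L]]
          paste0(
            if (length(re)) paste(names(re), collapse = " + ") else "0",
            " -> ",
            if (length(pr)) paste(names(pr), collapse = " + ") else "0"
          )
        }, ""),
        stringsAsFactors = FALSE
      ),
      rates = rates,
      params = params
    ),
    class = "tcs_reaction_network"
  )
}

#' @export
print.tcs_reaction_network <- function(x, ...) {
  cat("AtoSC mass-action reaction network:",
      ncol(x$stoichiometry), "rate laws over",
      nrow(x$stoichiometry), "species\n")
  print(x$reactions, ...)
  invisible(x)
}
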
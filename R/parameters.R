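#' @useDynLib atosensor
#' @keywords internal
"_PACKAGE"

# Canonical parameter order. This order is load-bearing: the compiled
# derivative routine indexes the parameter vector positionally.
.tcs_param_names <- c(
  "k_ap", "k_ad",
  "k_b1", "k_d1", "k_pt",
  "k_b2", "k_d2", "k_ph",
  "k_b3", "k_d3",
  "k_bnd", "k_unbnd",
  "k_lgexp", "k_pmgexp",
  "k_trl", "k_mat", "d_m", "d_g",
  "S_tot", "C_tot", "P_tot"
)

# Totals must be strictly positive for a runnable model.
.tcs_total_names <- c("S_tot", "C_tot", "P_tot")

# Reporter-cascade parameters: excluded from sensitivity rankings because a
# biosensor can be rebuilt with any reporter; their values only scale output.
.tcs_reporter_names <- c("k_trl", "k_mat", "d_m", "d_g")

#' Rate constants and conserved totals of the AtoSC two-component system model
#'
#' Constructs a validated parameter set for the mechanistic AtoSC model.  The
#' model couples the AtoS histidine kinase (HK), the AtoC response regulator
#' (RR) and the Pato promoter through mass-action phosphotransfer kinetics,
#' with a one-mRNA / one-maturation-step GFP reporter cascade downstream.
#'
#' Defaults are a nominal operating point chosen to give a sigmoidal,
#' high-fold-change dose-response in `k_ap`; they are stand-in values (the
#' point of the package is screening over ranges, not any single calibrated
#' set).  Time and concentration units are arbitrary but consistent.
#'
#' @param ... named replacements for any of the parameters below.
#'
#' @section Parameters:
#' \describe{
#'   \item{k_ap}{HK autophosphorylation rate (1/time); the acetoacetate proxy.}
#'   \item{k_ad}{HK autodephosphorylation rate (1/time).}
#'   \item{k_b1, k_d1}{association/dissociation of phospho-HK with RR.}
#'   \item{k_pt}{phosphotransfer rate, phospho-HK:RR complex -> HK + phospho-RR.}
#'   \item{k_b2, k_d2}{association/dissociation of HK with phospho-RR.}
#'   \item{k_ph}{phosphatase rate, HK:phospho-RR complex -> HK + RR.}
#'   \item{k_b3, k_d3}{association/dissociation of HK with RR (dead-end complex).}
#'   \item{k_bnd, k_unbnd}{phospho-RR binding/unbinding at the Pato promoter.}
#'   \item{k_lgexp}{leaky transcription rate from free Pato.}
#'   \item{k_pmgexp}{induced transcription rate from occupied Pato.}
#'   \item{k_trl, k_mat, d_m, d_g}{reporter cascade: translation, GFP
#'     maturation, mRNA degradation, GFP degradation/dilution.}
#'   \item{S_tot, C_tot, P_tot}{conserved totals of HK, RR and promoter.}
#' }
#'
#' @return a named numeric vector of class `tcs_parameters`.
#' @examples
#' p <- tcs_parameters(k_ap = 0.05, C_tot = 4)
#' p["k_ap"]
#' @export
tcs_parameters <- function(...) {
  p <- c(
    k_ap = 0.01, k_ad = 0.1,
    k_b1 = 1, k_d1 = 0.1, k_pt = 1,
    k_b2 = 1, k_d2 = 0.1, k_ph = 1,
    k_b3 = 1, k_d3 = 0.1,
    k_bnd = 10, k_unbnd = 0.1,
    k_lgexp = 0.01, k_pmgexp = 1,
    k_trl = 1, k_mat = 1, d_m = 0.5, d_g = 0.1,
    S_tot = 1, C_tot = 2, P_tot = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments to tcs_parameters() must be named")
    unknown <- setdiff(names(dots), .tcs_param_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  p <- p[.tcs_param_names]
  class(p) <- "tcs_parameters"
  validate_tcs_parameters(p)
  p
}

#' Validate a TCS parameter set
#'
#' Every parameter must be finite and non-negative; the conserved totals
#' `S_tot`, `C_tot`, `P_tot` must be strictly positive.
#'
#' @param params object coercible to [tcs_parameters()].
#' @return the validated parameters, invisibly.
#' @export
validate_tcs_parameters <- function(params) {
  p <- unclass(params)
  if (!all(.tcs_param_names %in% names(p)))
    stop("missing parameter(s): ",
         paste(setdiff(.tcs_param_names, names(p)), collapse = ", "))
  p <- p[.tcs_param_names]
  bad <- names(p)[!is.finite(p)]
  if (length(bad))
    stop("non-finite parameter(s): ", paste(bad, collapse = ", "))
  bad <- names(p)[p < 0]
  if (length(bad))
    stop("negative parameter(s): ", paste(bad, collapse = ", "))
  bad <- .tcs_total_names[p[.tcs_total_names] <= 0]
  if (length(bad))
    stop("totals must be strictly positive: ", paste(bad, collapse = ", "))
  invisible(params)
}

#' @export
print.tcs_parameters <- function(x, ...) {
  cat("AtoSC TCS model parameters\n")
  print(unclass(x), ...)
  invisible(x)
}

# File keys follow the field naming (S, C, pato for the totals; reporter
# constants prefixed "rep_"); internal names use *_tot and bare reporter names.
.tcs_file_key <- c(
  k_ap = "k_ap", k_ad = "k_ad",
  k_b1 = "k_b1", k_d1 = "k_d1", k_pt = "k_pt",
  k_b2 = "k_b2", k_d2 = "k_d2", k_ph = "k_ph",
  k_b3 = "k_b3", k_d3 = "k_d3",
  k_bnd = "k_bnd", k_unbnd = "k_unbnd",
  k_lgexp = "k_lgexp", k_pmgexp = "k_pmgexp",
  k_trl = "rep_k_trl", k_mat = "rep_k_mat", d_m = "rep_d_m", d_g = "rep_d_g",
  S_tot = "S", C_tot = "C", P_tot = "pato"
)

#' Read or write a TCS parameter set as flat YAML or JSON
#'
#' Files are flat maps keyed by the conventional short names: `k_ap` ...
#' `k_unbnd`, `S`, `C`, `pato` for the totals, and `rep_k_trl`, `rep_k_mat`,
#' `rep_d_m`, `rep_d_g` for the reporter cascade.  Format is chosen by file
#' extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path file path.
#' @param params a [tcs_parameters()] object (for writing).
#' @return `read_tcs_parameters` returns a `tcs_parameters` object;
#'   `write_tcs_parameters` returns `path` invisibly.
#' @export
read_tcs_parameters <- function(path) {
  vals <- .read_flat_map(path)
  key2int <- stats::setNames(names(.tcs_file_key), .tcs_file_key)
  unknown <- setdiff(names(vals), names(key2int))
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(as.numeric(unlist(vals))),
                          key2int[names(vals)])
  do.call(tcs_parameters, args)
}

#' @rdname read_tcs_parameters
#' @export
write_tcs_parameters <- function(params, path) {
  validate_tcs_parameters(params)
  vals <- as.list(stats::setNames(as.numeric(params),
                                  .tcs_file_key[.tcs_param_names]))
  .write_flat_map(vals, path)
  invisible(path)
}

.read_flat_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported extension '", ext, "' (use yaml or json): ", path)
}

.write_flat_map <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else stop("unsupported extension '", ext, "' (use yaml or json): ", path)
}
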
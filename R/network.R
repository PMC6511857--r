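## Assembly of the latch reaction network.
##
## Species (proteins/mRNA in uM, switch DNA in AU summing to 1):
##   m_int, m_rdf, m_tet          mRNAs
##   int_mono, int_dim            integrase monomer and dimer
##   int_dim_rdf                  activated integrase-dimer:RDF complex
##   rdf, tetr                    free RDF and TetR
##   dna_pb, dna_lr               switch DNA in PB / LR configuration
##   syn_pb, syn_lr               synaptic complexes (PB + 2 dimers,
##                                LR + 2 activated complexes)
##   dna_pb_dead (optional)       PB with a dead-end bound dimer:RDF complex
##
## Scheme: integrase monomer <-> dimer; dimer + RDF <-> activated complex
## (stoichiometric RDF requirement); PB + 2 dimers <-> synapse -> LR +
## release; LR + 2 activated complexes <-> synapse -> PB + release.  RDF
## transcription is proportional to LR-configured DNA and repressed by TetR
## (delay circuit); TetR transcription is proportional to PB-configured DNA.

#' DNA-carrying species of a network
#'
#' @param network a \linkS4class{ReactionNetwork} (or missing to get the
#'   canonical name set).
#' @return character vector of DNA species names.
#' @export
dnaSpecies <- function(network) {
  base <- c("dna_pb", "dna_lr", "syn_pb", "syn_lr", "dna_pb_dead")
  if (missing(network)) return(base)
  intersect(base, network@species)
}

## LR-configured subset (synapses attributed to the configuration they hold;
## the PB->LR synapse still holds PB DNA, the LR->PB synapse holds LR)
lrSpecies <- function(network) intersect(c("dna_lr", "syn_lr"), network@species)

#' Hill repression of a promoter
#'
#' Promoter activity under a repressor:
#' \code{leak + (1 - leak) / (1 + (conc/K)^n)}, monotone non-increasing in
#' the repressor concentration, equal to 1 at zero repressor and to
#' \code{leak} at saturation.
#'
#' @param conc repressor concentration (µM), >= 0 (vectorised).
#' @param K half-maximal repression concentration (µM), > 0.
#' @param n Hill coefficient, >= 1.
#' @param leak residual activity at saturating repressor, in [0, 1].
#' @return promoter activity in \code{[leak, 1]}.
#' @examples
#' hillRepression(0, K = 0.1, n = 2)            # 1
#' hillRepression(0.1, K = 0.1, n = 4)          # 0.5 at conc == K
#' @export
hillRepression <- function(conc, K, n = 2, leak = 0) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be finite and >= 0")
  assertScalar(K, "K"); if (K <= 0) stop("'K' must be > 0")
  assertScalar(n, "n", lower = 1)
  assertScalar(leak, "leak", upper = 1)
  leak + (1 - leak) / (1 + (conc / K)^n)
}

#' Build the latch reaction network
#'
#' Encodes the full deterministic model: arabinose-gated integrase mRNA
#' production; RDF mRNA production proportional to LR-state DNA and (when the
#' TetR delay circuit is enabled) repressed by TetR; TetR mRNA production
#' proportional to PB-state DNA (absent when the circuit is disabled, in
#' which case RDF expression from LR is constitutive); translation,
#' degradation and dilution; integrase dimerisation; stoichiometric
#' dimer:RDF complexation; and the directional synapse/conversion reactions
#' in both directions.  Total switch DNA is conserved by construction.
#'
#' @param params a \linkS4class{LatchParams}.
#' @return a validated \linkS4class{ReactionNetwork}.
#' @examples
#' net <- buildNetwork(latchParams())
#' speciesNames(net)
#' @export
buildNetwork <- function(params) {
  stopifnot(is(params, "LatchParams"))
  validObject(params)
  p <- params
  species <- c("m_int", "m_rdf", "m_tet", "int_mono", "int_dim",
               "int_dim_rdf", "rdf", "tetr",
               "dna_pb", "dna_lr", "syn_pb", "syn_lr")
  if (p@dead_end_pb) species <- c(species, "dna_pb_dead")

  rx <- list()                       # name -> named stoichiometry vector
  add <- function(name, ...) rx[[name]] <<- c(...)
  s2 <- 2 * p@dna_um                 # uM of dimer/complex per AU of synapse
  s1 <- p@dna_um

  add("tx_int",  m_int = 1)
  add("tx_rdf",  m_rdf = 1)
  add("tx_tet",  m_tet = 1)
  add("tl_int",  int_mono = 1)
  add("tl_rdf",  rdf = 1)
  add("tl_tet",  tetr = 1)
  add("loss_m_int", m_int = -1)
  add("loss_m_rdf", m_rdf = -1)
  add("loss_m_tet", m_tet = -1)
  add("loss_int_mono", int_mono = -1)
  add("loss_int_dim", int_dim = -1)
  add("loss_int_dim_rdf", int_dim_rdf = -1)   # bound RDF is lost with it
  add("loss_rdf", rdf = -1)
  add("loss_tetr", tetr = -1)
  add("dimerise",   int_mono = -2, int_dim = 1)
  add("undimerise", int_dim = -1, int_mono = 2)
  add("rdf_bind",    int_dim = -1, rdf = -1, int_dim_rdf = 1)
  add("rdf_release", int_dim_rdf = -1, int_dim = 1, rdf = 1)
  add("syn_pb_assemble",    dna_pb = -1, syn_pb = 1, int_dim = -s2)
  add("syn_pb_disassemble", syn_pb = -1, dna_pb = 1, int_dim = s2)
  add("convert_pb_to_lr",   syn_pb = -1, dna_lr = 1, int_dim = s2)
  add("syn_lr_assemble",    dna_lr = -1, syn_lr = 1, int_dim_rdf = -s2)
  add("syn_lr_disassemble", syn_lr = -1, dna_lr = 1, int_dim_rdf = s2)
  add("convert_lr_to_pb",   syn_lr = -1, dna_pb = 1, int_dim_rdf = s2)
  if (p@dead_end_pb) {
    add("dead_end_bind",    dna_pb = -1, dna_pb_dead = 1, int_dim_rdf = -s1)
    add("dead_end_release", dna_pb_dead = -1, dna_pb = 1, int_dim_rdf = s1)
  }

  reactions <- names(rx)
  stoich <- matrix(0, length(species), length(reactions),
                   dimnames = list(species, reactions))
  for (j in seq_along(rx)) stoich[names(rx[[j]]), j] <- rx[[j]]

  tetOn <- p@tetr_circuit_enabled
  koff_rdf <- p@k_rdf_on * p@K_rdf
  tx_int_max <- p@k_tx_int * p@c_int
  tx_rdf_max <- p@k_tx_rdf * p@c_switch
  tx_tet_max <- p@k_tx_tetr * p@c_switch
  dm <- p@d_mrna + p@mu
  di <- p@d_int + p@mu
  dr <- p@d_rdf + p@mu
  dt <- p@d_tetr + p@mu
  dead <- p@dead_end_pb

  rateFun <- function(t, x, ara) {
    lr_dna <- x[["dna_lr"]] + x[["syn_lr"]]
    pb_dna <- x[["dna_pb"]] + x[["syn_pb"]]
    if (dead) pb_dna <- pb_dna + x[["dna_pb_dead"]]
    rep_tet <- if (tetOn)
      p@leak_tet + (1 - p@leak_tet) / (1 + (x[["tetr"]] / p@K_tet)^p@n_tet)
    else 1
    v <- c(
      tx_int = tx_int_max * (p@leak_bad + (1 - p@leak_bad) * ara),
      tx_rdf = tx_rdf_max * lr_dna * rep_tet,
      tx_tet = if (tetOn) tx_tet_max * pb_dna else 0,
      tl_int = p@k_tl_int * x[["m_int"]],
      tl_rdf = p@k_tl_rdf * x[["m_rdf"]],
      tl_tet = p@k_tl_tetr * x[["m_tet"]],
      loss_m_int = dm * x[["m_int"]],
      loss_m_rdf = dm * x[["m_rdf"]],
      loss_m_tet = dm * x[["m_tet"]],
      loss_int_mono = di * x[["int_mono"]],
      loss_int_dim = di * x[["int_dim"]],
      loss_int_dim_rdf = di * x[["int_dim_rdf"]],
      loss_rdf = dr * x[["rdf"]],
      loss_tetr = dt * x[["tetr"]],
      dimerise = p@k_dim * x[["int_mono"]]^2,
      undimerise = p@k_undim * x[["int_dim"]],
      rdf_bind = p@k_rdf_on * x[["int_dim"]] * x[["rdf"]],
      rdf_release = koff_rdf * x[["int_dim_rdf"]],
      syn_pb_assemble = p@k_syn_on * x[["dna_pb"]] * x[["int_dim"]]^2,
      syn_pb_disassemble = p@k_syn_off * x[["syn_pb"]],
      convert_pb_to_lr = p@k_cat_f * x[["syn_pb"]],
      syn_lr_assemble = p@k_syn_on * x[["dna_lr"]] * x[["int_dim_rdf"]]^2,
      syn_lr_disassemble = p@k_syn_off * x[["syn_lr"]],
      convert_lr_to_pb = p@k_cat_r * x[["syn_lr"]])
    if (dead)
      v <- c(v,
             dead_end_bind = p@k_dead_on * x[["dna_pb"]] * x[["int_dim_rdf"]],
             dead_end_release = p@k_dead_off * x[["dna_pb_dead"]])
    v
  }

  new("ReactionNetwork", species = species, stoich = stoich,
      reactions = reactions, rateFun = rateFun, params = params)
}

#' @describeIn buildNetwork species registry of a network
#' @param object a \linkS4class{ReactionNetwork}.
#' @export
setMethod("speciesNames", "ReactionNetwork", function(object) object@species)

#' @describeIn buildNetwork display a network
#' @export
setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions\n",
              length(object@species), length(object@reactions)))
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  TetR delay circuit:",
      if (object@params@tetr_circuit_enabled) "enabled" else "disabled", "\n")
})
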
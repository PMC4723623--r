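#' Published reference network-property table
#'
#' The network-property summary of the twelve berry-development
#' correlation networks (two cultivars x six developmental stages, node
#' universe of 115 metabolites) reported by the published study this
#' pipeline models. Used as an arithmetic anchor: the density and
#' node-accounting conventions of [summarizeTopology()] reproduce these
#' printed values exactly (`density = edges / choose(115, 2)` to the
#' printed 3 decimals, `connected + isolated = 115`).
#'
#' @return data.frame with columns `cultivar`, `stage`,
#'   `connected_nodes`, `isolated_nodes`, `edges`,
#'   `connected_components`, `diameter`, `average_path_length`,
#'   `density`, `cluster_coefficient`.
#' @examples
#' ref <- referenceTopology()
#' all(ref$connected_nodes + ref$isolated_nodes == 115)
#' @export
referenceTopology <- function() {
  path <- system.file("extdata", "reference_topology.tsv",
                      package = "berrynet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
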
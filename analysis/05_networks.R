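#!/usr/bin/env Rscript
# Drug-target interaction network analysis: the approved-drug kinase
# network realized from its printed degree histograms, popular targets
# and multitarget drugs, and the ICD C51-C58 disease-class subnetwork.

suppressMessages(library(dtprofiler))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)

deg <- approved_network_degrees()
net <- realize_bipartite(deg$drug, deg$target)
message("approved-drug network: ", nrow(net$drugs), " drugs, ",
        nrow(net$targets), " targets, ", nrow(net$interactions), " edges")
for (cls in c("drug", "target")) {
  h <- degree_histogram(net, cls)
  write.table(h, sprintf("results/network/degree_%s.tsv", cls), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("  ", cls, " degrees: ",
          paste(sprintf("%d:%d", h$degree, h$count), collapse = " "))
}
pop <- popular_nodes(net, "target", 8)
message("targets with degree > 8: ", paste(pop$id, pop$degree, collapse = ", "))
message("multitarget drugs (degree >= 2): ", nrow(multitarget_drugs(net)))
export_network(net, "results/network", basename = "approved")

sub_deg <- genital_cancer_subnet_degrees()
subnet <- realize_bipartite(sub_deg$drug, sub_deg$target, stage = "phase2",
                            target_cohort = "clinical_trial",
                            drug_prefix = "CLI", target_prefix = "CTG")
message("female-genital-organ cancer subnetwork (C51-C58): ",
        nrow(subnet$drugs), " drugs, ", nrow(subnet$targets), " targets")
export_network(subnet, "results/network", basename = "subnet_C51_C58")
write.table(degree_histogram(subnet, "target"),
            "results/network/subnet_degree_target.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done; exports under results/network/")
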
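# 50-molecule chemistry fixture set with frozen reference values
# (computed once with an independent cheminformatics toolkit).
fixture_smiles <- c(
  "CCO",
  "CC(C)O",
  "CCCCCCCC",
  "c1ccccc1",
  "Cc1ccccc1",
  "Oc1ccccc1",
  "Nc1ccccc1",
  "c1ccncc1",
  "c1ccc2ccccc2c1",
  "CC(=O)O",
  "CC(=O)OC",
  "CC(=O)N",
  "CC(=O)Nc1ccccc1",
  "CCN(CC)CC",
  "CN1CCC[C@H]1c1cccnc1",
  "ClC(Cl)(Cl)Cl",
  "FC(F)(F)c1ccccc1",
  "BrCCBr",
  "ICc1ccccc1",
  "CS(=O)(=O)C",
  "CSSC",
  "c1ccsc1",
  "c1cc[nH]c1",
  "c1ccoc1",
  "O=C1CCCCC1",
  "C1CCNCC1",
  "OCC(O)CO",
  "NC(=O)N",
  "N#Cc1ccccc1",
  "O=[N+]([O-])c1ccccc1",
  "CC(=O)Oc1ccccc1C(=O)O",
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "NCC(O)c1ccc(O)c(O)c1",
  "OC(=O)c1ccccc1O",
  "CCOP(=O)(OCC)OCC",
  "c1ccc2[nH]ccc2c1",
  "COc1ccccc1",
  "CCOCC",
  "CC#N",
  "CC=C",
  "C=CC=C",
  "C1CC1",
  "C1CCCCC1",
  "CC(C)(C)c1ccccc1",
  "OS(=O)(=O)O",
  "NS(=O)(=O)c1ccccc1",
  "Cn1cnc2c1cccc2",
  "O=C(O)CCCCC(=O)O",
  "CCCCN",
  "CC(N)C(=O)O"
)
# reference Wildman-Crippen values (independent implementation, frozen)
fixture_slogp_ref <- c(
  -0.001400,
  0.387100,
  3.366800,
  1.686600,
  1.995020,
  1.392200,
  1.268800,
  1.081600,
  2.839800,
  0.090900,
  0.179300,
  -0.508400,
  1.645000,
  1.348100,
  1.848300,
  2.552900,
  2.705400,
  1.776200,
  2.621600,
  -0.339200,
  1.627400,
  1.748100,
  1.014700,
  1.279600,
  1.519600,
  0.759900,
  -1.668100,
  -0.976200,
  1.558280,
  1.594800,
  1.310100,
  -1.029300,
  0.089900,
  1.090400,
  2.204000,
  2.167900,
  1.695200,
  1.042800,
  0.529880,
  1.192300,
  1.358400,
  1.170300,
  2.340600,
  2.984100,
  -0.652800,
  0.334000,
  1.573300,
  0.716000,
  0.745200,
  -0.581800
)
# reference unique-atom-set substructure counts (frozen)
fixture_fragment_ref <- list(
  hydroxyl = c(1, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 0, 0, 0, 1, 0, 3, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 2, 0, 1),
  carboxylic_acid = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 1),
  benzene_ring = c(0, 0, 0, 1, 1, 1, 1, 0, 2, 0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1, 0, 0, 0),
  methyl = c(1, 2, 2, 0, 1, 0, 0, 0, 0, 1, 2, 1, 1, 3, 1, 0, 0, 0, 0, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 3, 0, 0, 3, 0, 1, 2, 1, 1, 0, 0, 0, 3, 0, 0, 1, 0, 1, 1),
  aromatic_C = c(0, 0, 0, 6, 6, 6, 6, 5, 10, 0, 0, 0, 6, 0, 5, 0, 6, 0, 6, 0, 0, 4, 4, 4, 0, 0, 0, 0, 6, 6, 6, 5, 6, 6, 0, 8, 6, 0, 0, 0, 0, 0, 0, 6, 0, 6, 7, 0, 0, 0),
  n_nitrogen = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1, 1, 2, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 2, 1, 1, 0, 4, 1, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 2, 0, 1, 1),
  nitrile = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  sulfonamide = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
  ether_dialkyl = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  nitro = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  amide = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  halogen_on_sp3C = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 4, 3, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  alkene = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
)
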
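# Reference fixture specification, version 1.
#
# Every count here is a planted property of the synthetic inputs; the test
# suite and acceptance script recover them by running the screen, so each
# number is a regression surface rather than a hard-coded assertion.
name: reference
universe:
  membrane_size: 2202        # plasma-membrane protein universe
  foxp3_up_size: 1004        # FoxP3-upregulated signature
  treg_specific_size: 431    # Treg-specific signature
  overlap_foxp3: 173         # |membrane & foxp3_up|
  overlap_treg: 50           # |membrane & treg_specific|
  excluded_foxp3: 67         # known-checkpoint removals from the FoxP3 branch
  excluded_treg: 5           # known-checkpoint removals from the Treg branch
finalists:
  treg: [CEP55]
  foxp3: [CD38, EHD4, CD200R1, PRC1, RAPH1, CD86]
survivors:                   # round-2 survivors per branch (finalists first)
  treg: 18
  foxp3: 67
panel:
  targets: [CTLA4, PDCD1, LAG3, TIGIT, KLRG1, CD47, CD49B, CD96, HAVCR2, KIR3DL3]
  size: 25                   # reference inhibitory-checkpoint panel
datasets:                    # knockout datasets per perturbed target (16 total)
  CTLA4: 3
  PDCD1: 3
  TIGIT: 3
  KLRG1: 1
  LAG3: 1
  CD47: 1
  HAVCR2: 1
  CD49B: 1
  CD96: 1
  KIR3DL3: 1
panel_down:                  # panel genes down-called in <target>_KO_1
  CTLA4: 6                   # 6/25  -> 24%, high hierarchy
  PDCD1: 7                   # 7/25  -> 28%
  LAG3: 8                    # 8/25  -> 32%
  TIGIT: 8
  KLRG1: 8
  CD47: 5                    # 5/25 = 20% exactly -> low under strict >
  CD49B: 4
  CD96: 2
  HAVCR2: 3
  KIR3DL3: 1
candidate_down:              # candidate down-call counts in named datasets;
  TIGIT_KO_1: 41             # allocation covers every non-finalist survivor
  KLRG1_KO_1: 16
  CD47_KO_1: 12
  HAVCR2_KO_1: 9
  CD49B_KO_1: 21
ligands:
  final_counts:              # retained ligands per finalist receptor
    CEP55: 10                # includes the CEP55 homodimer
    CD38: 2
    EHD4: 11
    CD200R1: 2
    PRC1: 22
    RAPH1: 3
    CD86: 7
  n_distinct: 46             # distinct union across receptors
  cross_branch_shared: 4     # ligands shared between the two branches
  homodimer: true            # the Treg receptor lists itself as a partner
  treg_partners: 274         # interaction partners, Treg-branch receptor
  treg_membrane: 39          # of which on the plasma membrane
  foxp3_partners: 1190       # distinct partners, FoxP3-branch receptors
  foxp3_membrane: 139
  treg_double_attr: 2        # membrane survivors matching two APC marker sets
  foxp3_double_attr: 28
apc_marker_sizes:
  macrophage: 503
  monocyte: 225
  B_cell: 1200
  dendritic_cell: 481
tolerogenic_ids: [M2_MACRO, B1_BCELL, TOL_DC, AGED_MONO]
modulation:
  dataset_id: PDL1_KD
  altered: 30                # final ligands altered in the knock-down
  up: 20                     # of which upregulated
celltype:
  cells_per_type: 40
  noise_sd: 0.2
noise:
  background_size: 600       # null genes added to every DE table
  lfc_sd: 1.0                # spread of null log2 fold-changes
alpha: 0.05
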
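# Shared vocabulary of the claims model (sourced first).

# Drug classes used for acute vs preventive migraine treatment. Any molecule
# outside the codelist is carried as class "other" and ignored by the
# migraine-treatment logic.
ACUTE_CLASSES <- c("acetaminophen_nsaid", "triptan", "ergotamine")
PREVENTIVE_CLASSES <- c("anti_cgrp_mab", "antiepileptic", "antidepressant",
                        "beta_blocker", "ca_channel_blocker")
CONVENTIONAL_PREVENTIVE <- setdiff(PREVENTIVE_CLASSES, "anti_cgrp_mab")

FACILITY_BANDS <- c("CP_0_19", "HP_20_99", "HP_100_199", "HP_200_299",
                    "HP_300_499", "HP_500_plus")

# The four groups pooled into "any cardiovascular comorbidity".
CARDIOVASCULAR_GROUPS <- c("cerebrovascular_disease", "hypertension",
                           "ischemic_heart_disease",
                           "peripheral_vascular_disease")
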
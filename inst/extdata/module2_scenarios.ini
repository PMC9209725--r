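# Knockout / rescue scenarios for the redox-switch module.
# Convention: knockout = synthesis or activation rate set to zero;
# for fixed totals, the total set to zero. Extend freely.

[gls_KO]
description = glutaminase knockout; Cdh1->Gls->glutamate->Ca loop broken
expect = reversible transition, lower ROS branch, SN1 right
k_sgls = 0

[cycb_KO]
description = CycB knockout; CycB-Cdh1 mutual antagonism broken
expect = reversible transition, lower ROS branch, SN1 right
k_scycb = 0
k_scyc = 0

[p25_inhibition]
description = p25-Cdk5 inhibition
expect = no pathological transition
k_sp25 = 0

[double_KO]
description = glutaminase AND CycB knockout
expect = no pathological transition
k_sgls = 0
k_scycb = 0
k_scyc = 0

[cdh1_inhibitor]
description = APC/C-Cdh1 inhibitor
expect = pathological state without amyloid-beta
k_acdh1 = 0

[antioxidant]
description = membrane-permeable antioxidant (raised basal scavenging)
expect = normal state despite amyloid-beta
k_anadphb = 2

[glutamate_excitotoxicity]
description = excess basal glutamate synthesis
expect = pathological transition without amyloid-beta
k_sglub = 1

[cycb_overexpression]
description = CycB overexpression
expect = pathological transition without amyloid-beta
k_scycb = 2
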
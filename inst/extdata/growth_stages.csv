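stage,h_cm,theta_deg,delta_deg,E0,Df,alpha
three_leaf,5,33.8,0,1,0.15,0.1
flowering,23,30.4,0,1,0.15,0.1
podding,113,27.0,0,1,0.15,0.1
seed_filling,101,21.4,0,1,0.15,0.1
maturity,100,13.9,0,1,0.15,0.1
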
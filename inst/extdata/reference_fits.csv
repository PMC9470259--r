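model,family,term,estimate,ci_low,ci_high,n_obs
plasticity,binomial-logit,(Intercept),-0.56,-0.57,-0.55,510830
plasticity,binomial-logit,sensitive,2.21,2.20,2.23,510830
n_phenotypes,ztnb-log,(Intercept),1.04,1.04,1.04,510830
n_phenotypes,ztnb-log,sensitive,0.66,0.66,0.66,510830
uncertainty,quasibinomial-logit,(Intercept),2.30,2.30,2.31,808981
uncertainty,quasibinomial-logit,sensitive,-1.43,-1.44,-1.43,808981
viability,binomial-logit,(Intercept),-0.92,-0.95,-0.88,95676
viability,binomial-logit,plastic,-0.34,-0.38,-0.30,95676
phen_by_cost,ztnb-log,(Intercept),2.15,2.13,2.17,80333
phen_by_cost,ztnb-log,transcriptomes,-0.04,-0.06,-0.03,80333
phen_by_cost,ztnb-log,cost,-0.56,-0.58,-0.54,80333
phen_by_cost,ztnb-log,transcriptomes:cost,0.33,0.31,0.34,80333
tlen,linear,(Intercept),898.92,895.64,902.20,8055548
tlen,linear,plastic,87.16,81.73,92.60,8055548
tlen,linear,sensitive,925.47,921.81,929.13,8055548
tlen,linear,plastic:sensitive,55.78,50.07,61.49,8055548
io,poisson-log,(Intercept),3.49,3.48,3.50,487705
io,poisson-log,plastic,0.68,0.67,0.69,487705
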
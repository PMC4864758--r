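id,type,p1,p2,p3,p4,p5,p6,printed,tolerance,reproducible,note
cohens_d_td_congruent_vs_texture,cohens_d,2.91,14,NA,NA,NA,NA,0.78,0.005,TRUE,typical group T+D+ vs T+
cohens_d_td_congruent_vs_disparity,cohens_d,2.96,14,NA,NA,NA,NA,0.79,0.005,TRUE,typical group T+D+ vs D+
cohens_d_asd_congruent_vs_disparity,cohens_d,4.84,16,NA,NA,NA,NA,1.21,0.005,TRUE,ASD group T+D+ vs D+
cohens_d_td_incongruent_vs_texture,cohens_d,-4.06,14,NA,NA,NA,NA,1.09,0.005,TRUE,typical group T+D- vs T+
cohens_d_td_incongruent_vs_disparity,cohens_d,-2.31,14,NA,NA,NA,NA,0.62,0.005,TRUE,typical group T+D- vs D-
cohens_d_asd_incongruent_vs_texture,cohens_d,-2.78,16,NA,NA,NA,NA,0.70,0.005,TRUE,ASD group T+D- vs T+
cohens_d_asd_incongruent_vs_disparity,cohens_d,-0.18,16,NA,NA,NA,NA,0.05,0.0051,TRUE,ASD group T+D- vs D-; computed 0.045 sits on the 2 d.p. rounding boundary
cohens_d_asd_congruent_vs_texture,cohens_d,2.767,16,NA,NA,NA,NA,0.39,0.005,FALSE,printed value inconsistent with |t|/sqrt(n) = 0.69; documented anomaly
partial_eta_sq_condition,partial_eta_sq,4.12,1,28,NA,NA,NA,0.13,0.005,TRUE,condition main effect
partial_eta_sq_group,partial_eta_sq,1.16,1,28,NA,NA,NA,0.04,0.005,TRUE,group main effect
partial_eta_sq_interaction,partial_eta_sq,0.35,1,28,NA,NA,NA,0.012,0.0005,TRUE,group x condition interaction
pooled_t_performance_iq,pooled_t,108.8,11.9,16,113.5,8.8,14,1.21,0.02,TRUE,performance IQ group comparison
pooled_t_fullscale_iq,pooled_t,104.5,10.7,16,116.7,8.3,14,3.44,0.02,TRUE,full-scale IQ group comparison
pooled_t_verbal_iq,pooled_t,99.8,13.3,16,116.1,8.5,14,3.95,0.02,TRUE,verbal IQ group comparison
dual_test_alpha,dual_alpha,0.05,NA,NA,NA,NA,NA,0.0025,1e-12,TRUE,joint type-I bound for the dual planned comparison
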
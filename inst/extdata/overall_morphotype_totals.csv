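# Study-wide interaction totals per insect morphotype, pooled over all
# twelve sites, both plot spatial configurations and all four observation
# rounds; plant identity is pooled ("community").
site_id,landscape_context,round,plot_id,spatial_config,plant_species,insect_morphotype,visit_count
study-total,pooled,1,all,pooled,community,solitary bees,5038
study-total,pooled,1,all,pooled,community,Apis mellifera,36
study-total,pooled,1,all,pooled,community,bumblebees,5567
study-total,pooled,1,all,pooled,community,Coleoptera,565
study-total,pooled,1,all,pooled,community,Lepidoptera,118
study-total,pooled,1,all,pooled,community,Syrphidae,4789
study-total,pooled,1,all,pooled,community,other flies,1686
study-total,pooled,1,all,pooled,community,bugs,32
study-total,pooled,1,all,pooled,community,other Hymenoptera,26
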
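table,cell,expected,tolerance
overlap,MW:Smith|RB:Smith,0.85,0.01
overlap,MW:Sheep|RB:Sheep,0.57,0.01
overlap,RB:Sheep|RB:Smith,0.72,0.01
overlap,MW:Sheep|MW:Smith,0.59,0.01
richness,median_all,10,0
richness,max_all,17,0
group_size,MW:Smith,11,0
group_size,MW:Sheep,20,0
group_size,RB:Smith,6,0
group_size,RB:Sheep,20,0
coefficient,Hydropsychidae|stream,2.413,0.01
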
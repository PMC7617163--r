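label,synonyms,group,case_sensitive
Morris water maze,water maze|MWM|Morris maze,spatial learning,
Barnes maze,,spatial learning,
radial arm maze,,spatial learning,
Y-maze,Y maze alternation,working memory,
novel object recognition,NOR task,recognition memory,
passive avoidance,,aversive learning,
fear conditioning,contextual fear conditioning,aversive learning,
open field test,open field,locomotion and anxiety,
elevated plus maze,EPM test,locomotion and anxiety,
rotarod,rota-rod,motor function,
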
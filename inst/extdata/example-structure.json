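{"forms":[{"form_id":"subject","repeatable":false,"questions":[{"qid":"A0.P0.F1.G1.Q1","dtype":"string"},{"qid":"A0.P0.F1.G1.Q2","dtype":"text"},{"qid":"A0.P0.F1.G1.Q3","dtype":"integer"},{"qid":"A0.P0.F1.G1.Q4","dtype":"float"},{"qid":"A0.P0.F1.G1.Q5","dtype":"date"},{"qid":"A0.P0.F1.G1.Q6","dtype":"datetime"},{"qid":"A0.P0.F1.G1.Q7","dtype":"time"},{"qid":"A0.P0.F1.G1.Q8","dtype":"boolean"},{"qid":"A0.P0.F1.G1.Q9","dtype":"categorical"},{"qid":"A0.P0.F1.G3.Q1","dtype":"float"},{"qid":"A0.P0.F1.G3.Q2","dtype":"float"}]},{"form_id":"hospitalization","repeatable":false,"questions":[{"qid":"A0.P0.F2.G1.Q1","dtype":"integer"},{"qid":"A0.P0.F2.G1.Q2","dtype":"float"}]},{"form_id":"followup","repeatable":true,"questions":[{"qid":"A0.P0.F3.G1.Q1","dtype":"date"},{"qid":"A0.P0.F3.G1.Q2","dtype":"float"},{"qid":"A0.P0.F3.G1.Q3","dtype":"categorical"}]},{"form_id":"qol","repeatable":true,"questions":[{"qid":"A0.P0.F4.G1.Q1","dtype":"integer"},{"qid":"A0.P0.F4.G1.Q2","dtype":"integer"}]}]}
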
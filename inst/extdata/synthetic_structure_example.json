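{"id":"synthetic_1pgb_example","length":56,"ss":"CEEEEEEECCCCEEEEEEECCCHHHHHHHHHHHHHHHCCCCEEEEECCCCEEEEEC","contacts":[[0,9],[0,11],[1,18],[1,25],[1,26],[2,11],[2,17],[2,28],[3,11],[3,16],[3,36],[4,15],[4,45],[4,51],[5,14],[5,25],[5,29],[5,39],[5,40],[6,13],[6,49],[7,12],[8,27],[8,45],[9,15],[9,22],[10,37],[11,17],[11,52],[12,28],[12,30],[12,34],[12,43],[13,38],[13,54],[14,34],[14,44],[14,45],[15,18],[15,28],[15,30],[15,44],[16,28],[16,37],[16,43],[16,48],[16,54],[17,41],[17,42],[18,26],[18,38],[18,41],[18,46],[19,30],[19,32],[19,38],[19,46],[19,47],[20,36],[20,45],[21,33],[22,25],[22,26],[22,36],[22,41],[22,43],[22,48],[22,49],[22,52],[23,26],[23,27],[23,35],[23,36],[23,44],[24,27],[24,28],[24,44],[24,51],[25,28],[25,29],[26,29],[26,30],[26,34],[27,30],[27,31],[27,33],[27,44],[27,47],[28,31],[28,32],[28,49],[28,51],[29,32],[29,33],[29,35],[30,33],[30,34],[30,44],[31,34],[31,35],[31,37],[32,35],[32,36],[33,36],[33,50],[33,52],[34,47],[34,50],[35,50],[40,47],[40,50],[40,54],[41,54],[41,55],[42,53],[43,52],[44,51],[44,54],[44,55],[45,50]],"n_hbonds":28}
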
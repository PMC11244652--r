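{"nodes":[{"id":"inlet","x_um":0,"y_um":0},{"id":"outlet","x_um":6000,"y_um":0},{"id":"ti1","x_um":500,"y_um":750},{"id":"to1","x_um":500,"y_um":2250},{"id":"ti2","x_um":2000,"y_um":750},{"id":"to2","x_um":2000,"y_um":2250},{"id":"ti3","x_um":4000,"y_um":750},{"id":"to3","x_um":4000,"y_um":2250},{"id":"ti4","x_um":5500,"y_um":750},{"id":"to4","x_um":5500,"y_um":2250},{"id":"bi1","x_um":500,"y_um":-750},{"id":"bo1","x_um":500,"y_um":-2250},{"id":"bi2","x_um":2000,"y_um":-750},{"id":"bo2","x_um":2000,"y_um":-2250},{"id":"bi3","x_um":4000,"y_um":-750},{"id":"bo3","x_um":4000,"y_um":-2250},{"id":"bi4","x_um":5500,"y_um":-750},{"id":"bo4","x_um":5500,"y_um":-2250}],"segments":[{"id":"inner_t1","node_a":"ti1","node_b":"ti2","diameter_um":500,"zone_hint":"high"},{"id":"inner_t2","node_a":"ti2","node_b":"ti3","diameter_um":500,"zone_hint":"high"},{"id":"inner_t3","node_a":"ti3","node_b":"ti4","diameter_um":500,"zone_hint":"high"},{"id":"outer_t1","node_a":"to1","node_b":"to2","diameter_um":500,"zone_hint":"mid"},{"id":"outer_t2","node_a":"to2","node_b":"to3","diameter_um":500,"zone_hint":"mid"},{"id":"outer_t3","node_a":"to3","node_b":"to4","diameter_um":500,"zone_hint":"mid"},{"id":"vert_t1","node_a":"ti1","node_b":"to1","diameter_um":500,"zone_hint":"low"},{"id":"vert_t2","node_a":"ti2","node_b":"to2","diameter_um":500,"zone_hint":"low"},{"id":"vert_t3","node_a":"ti3","node_b":"to3","diameter_um":500,"zone_hint":"low"},{"id":"vert_t4","node_a":"ti4","node_b":"to4","diameter_um":500,"zone_hint":"low"},{"id":"feed_in_ti","node_a":"inlet","node_b":"ti1","diameter_um":500,"zone_hint":null},{"id":"feed_in_to","node_a":"inlet","node_b":"to1","diameter_um":500,"zone_hint":null},{"id":"feed_out_ti","node_a":"ti4","node_b":"outlet","diameter_um":500,"zone_hint":null},{"id":"feed_out_to","node_a":"to4","node_b":"outlet","diameter_um":500,"zone_hint":null},{"id":"inner_b1","node_a":"bi1","node_b":"bi2","diameter_um":500,"zone_hint":"high"},{"id":"inner_b2","node_a":"bi2","node_b":"bi3","diameter_um":500,"zone_hint":"high"},{"id":"inner_b3","node_a":"bi3","node_b":"bi4","diameter_um":500,"zone_hint":"high"},{"id":"outer_b1","node_a":"bo1","node_b":"bo2","diameter_um":500,"zone_hint":"mid"},{"id":"outer_b2","node_a":"bo2","node_b":"bo3","diameter_um":500,"zone_hint":"mid"},{"id":"outer_b3","node_a":"bo3","node_b":"bo4","diameter_um":500,"zone_hint":"mid"},{"id":"vert_b1","node_a":"bi1","node_b":"bo1","diameter_um":500,"zone_hint":"low"},{"id":"vert_b2","node_a":"bi2","node_b":"bo2","diameter_um":500,"zone_hint":"low"},{"id":"vert_b3","node_a":"bi3","node_b":"bo3","diameter_um":500,"zone_hint":"low"},{"id":"vert_b4","node_a":"bi4","node_b":"bo4","diameter_um":500,"zone_hint":"low"},{"id":"feed_in_bi","node_a":"inlet","node_b":"bi1","diameter_um":500,"zone_hint":null},{"id":"feed_in_bo","node_a":"inlet","node_b":"bo1","diameter_um":500,"zone_hint":null},{"id":"feed_out_bi","node_a":"bi4","node_b":"outlet","diameter_um":500,"zone_hint":null},{"id":"feed_out_bo","node_a":"bo4","node_b":"outlet","diameter_um":500,"zone_hint":null}],"inlet":"inlet","outlet":"outlet","follicles":[{"x_um":1500,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":2000,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":2500,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":3000,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":3500,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":4000,"y_um":0,"diameter_um":250,"depth_um":2000},{"x_um":4500,"y_um":0,"diameter_um":250,"depth_um":2000}]}
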